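---
title: "Methods: the graph positional Burrows–Wheeler transform in gpbwt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the graph positional Burrows–Wheeler transform in gpbwt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpbwt)
```

This vignette records the model the package implements, the choices made
where the design was genuinely open, the parameters that matter, and what
the synthetic-data generators do and do not emulate. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The model

A genome graph is bidirected: each node carries a DNA label and two *sides*
(ends), and edges join sides, so sequence can be entered from either
direction and structural variation (inversions, loops) is representable.
Node `k` has left side `2k − 1` and right side `2k`; this odd/even numbering
is a package convention — any total order on sides would do, but fixing one
makes every index bit-reproducible, and the convention keeps `opposite()`
and `node_of()` arithmetic. The *null side* 0 orders before every real side
and marks thread termination.

A haplotype (fragment) is a *thread*: an alternating side walk
`[t0, t1, …, t(2N+1)]` where consecutive even/odd pairs are the two sides of
one node and each `{t(2i+1), t(2i+2)}` is an edge. Threads are
*ambisequences* — a walk and its reverse are the same haplotype — so every
API that needs a unique representative uses the lexicographically smaller
orientation (`canonical_orientation()`). Lexicographic minimality is itself
a choice (any canonical rule works); it makes thread multisets comparable by
string keys, which the tests lean on.

For each side `s` the index stores `B_s[]`: over all visits of stored
orientations to `s`, *sorted by reversed history* (the side sequence before
the visit, reversed), the side each visit's thread enters its next node on.
Sorting by reversed history is what makes the structure a BWT relative: all
orientations that arrived the same way sit in a contiguous block, and the
block structure is preserved from each side to the next ("ribbons"). The
`c()` function — for an oriented edge `(x, s)`, the first `B_s[]` index of a
visit arriving via `{x, s}` — is not stored as such but materialized as a
per-side count of starting orientations plus per-oriented-edge usage
counts; any `c` value is then a prefix sum over the adjacency list of `s`,
taken in ascending side order. This is why `adjacent_sides()` sorts, and why
the graph must be treated as immutable once an index exists over it.

The navigation primitive is

```
where_to(s, i, s') = c(opposite(s), s') + rank_{s'}(B_s[], i)
```

the LF-mapping analogue. One function serves both extraction (which passes
the decoded `B` entry as `s'`) and counting (which passes the query's next
visit). An arrival index computed this way is interpreted as an index into
the B array of the *next entry side* `s'` — the only interpretation under
which the worked ten-side example in the test suite round-trips — and this
is asserted exactly by the acceptance tests.

### Ties, and why copy-compression works

Visits with *identical* reversed histories are ordered by reverse insertion
order: a newly embedded orientation's start entry goes to position 0 of its
first B array, before previously embedded starts, and stable propagation
through `where_to` preserves that relative order downstream. Counts are
unaffected by any tie rule. One structural consequence matters: embedding an
exact copy of a thread *immediately after* the original places every copy
entry adjacent to the original's, so run counts stay constant while run
lengths grow — the basis of the claim that additional identical samples are
nearly free. If copies are interleaved with other threads instead, start
entries at shared start sides can alternate and split runs; the test suite
therefore duplicates panels grouped per thread (`rep(panel, each = k)`),
which is also how a caller would re-embed a panel.

### Run-length arrays

`B_s[]` entries are stored as small *local codes* — code `j` means the j-th
side reachable by one edge hop from `opposite(s)`, code 0 the null side —
keeping each array's alphabet at the node's degree rather than the graph's
side count. The backing store (`rle_array`) is a maximal-run
`(value, length)` list supporting 0-based `value_at`, `rank_before` and
`insert_at`, with canonical form enforced at all times so equal logical
content is `identical()` and serializes byte-identically. Rank and insert
scan the run list with vectorized cumulative sums, i.e. cost linear in the
*number of runs*, not in array length; linkage keeps run counts small, and
at the scales this package targets (panels of tens to thousands of
haplotypes over graphs of up to a few thousand sides) the vectorized linear
scan was measured to beat maintaining auxiliary search structures. No
wavelet tree or select support is provided: the index needs exactly rank,
point access and insert.

### Embedding, extraction, counting

`embed_thread()` embeds both orientations, canonical first — both must be
present for queries to be orientation-symmetric. Each orientation is
embedded visit by visit: insert the start entry at position 0, then
alternately bump the arriving edge's usage count, locate the next insertion
point with `where_to`, and insert the next code. Validation happens before
any mutation, so a failed embed leaves the index unchanged.

`extract_orientations()` starts one trace per starting slot per side
(`thread_starts()` is the minimum of `c(x, s)` over incident edges, or
`|B_s[]|` for isolated sides) and follows `where_to` to the null side; a
dangling continuation raises a corruption error naming the side and index.
`extract_threads()` canonicalizes, checks every canonical form has even
multiplicity, and halves.

`count_subthread()` is backward search: the range starts as all of
`B_{t0}[]` and both endpoints are mapped through `where_to` per visit;
`g − f` at the end is the occurrence count. Two deliberate contract choices:
a query whose consecutive sides are not joined by any edge returns 0 rather
than erroring (a mapped read's path may simply be consistent with no
haplotype — that is an answer, not an exception), while structural nonsense
(odd length, non-opposite node pairs) errors. A single-node query
`[s, opposite(s)]` returns `|B_s[]|`, i.e. all visits through `s`.
`search_start()`/`extend_search()` expose the same recurrence one step at a
time so a streaming caller can lengthen a query without restarting.

### Batch construction

On graphs where every edge joins a right side to a left side of a different
node and the induced directed graph is acyclic (`dag_orientation()`), each
orientation enters nodes on left sides only (forward) or right sides only
(reverse), and visits any side at most once. `batch_embed()` exploits this:
it processes left sides in topological order (then right sides in reverse
order for the reverse orientations), concatenates each side's newly
starting orientations — ordered exactly as the incremental tie-break would
order them — with the per-edge arrival lists in adjacency order, emits the
B array in one shot, and stably partitions the visits by next side into the
outgoing lists. Equality with the incremental path is *byte equality of the
serialized index*, asserted over randomized panels; the incremental
algorithm is the executable ground truth. "Directed acyclic" has no
canonical meaning for bidirected graphs, so the right-to-left edge rule
above is this package's operationalization; graphs failing it get an
explicit failure value naming an offending edge or cycle, and `batch_embed`
refuses them with a pointer to `embed_thread`.

Peak additional state is one record per thread visit (`O(M·N)` for M
threads of length N), all in memory; no external-memory construction is
attempted.

## Graph construction and haplotype import

`graph_from_variants()` implements the textbook recipe: break the reference
chain so each variant's reference allele is one node, add the alternate
node, attach its sides to everything attached to the reference allele's
sides. Node ids are assigned in reference order with each alternate
directly after its reference node (determinism of serialized output);
adjacent variants produce no empty nodes — flanks connect directly, and
because alternates attach to whatever is *currently* incident, alternates
of adjacent sites become connected automatically. Variants must not
partially overlap; several alternates over one identical interval are
allowed (that is what split multiallelic records become). VCF positions are
converted to 0-based half-open internally.

`import_phased_vcf()` walks the reference node chain per sample and
haplotype, substituting alternate nodes where the phased genotype selects
them, and *splits* the thread wherever it cannot continue validly:
heterozygous unphased genotypes (phase unknown; homozygous `0/0`/`1/1` are
unambiguous and do not split), missing calls, haploid calls in diploid
import — all of which skip the variant site — and missing edges between
consecutive chosen nodes, where the new piece keeps the offending node. No
semantic reconciliation of conflicting alleles is attempted: splitting is
the only fallback, and per-reason tallies are reported. The trigger list is
deliberately closed; anything else is an error, not a silent split.

## Synthetic data

Two generators exercise the index end to end.

`simulate_haplotype_panel()` emulates linkage with a mosaic copying
process: founders draw alleles independently (probability 1/2), later
haplotypes copy a uniformly chosen earlier haplotype, re-choosing the
template with `switch_prob` per variant (recombination analogue) and
flipping the copied allele with `flip_prob` (mutation analogue). Defaults
`switch_prob = 0.1`, `flip_prob = 0.01` give panels that are clearly
correlated but not degenerate at the 5–10-variant scale of most tests. This
is *not* a coalescent: allele frequencies, LD decay with distance and
recombination hotspots are not calibrated to any population. What passing
tests show is therefore structural — round trips, count agreement,
batch/incremental identity, run-length behaviour — not population-genetic
realism.

`random_walk()` starts at a side chosen uniformly over all sides, crosses
the node, leaves by an edge chosen uniformly among those incident on the
exit side, and stops when the accumulated label length reaches the target;
a dead end is a failure value and the caller resamples (default budget 20
tries). The start/step distributions are package choices; consistency
*rates* of random walks against a panel depend on them and are asserted
only for determinism and sanity, never against external figures.
`drop_ambiguous_walks()` removes walks whose oriented sequence contains two
or more consecutive `N`s.

## Problem sizes and tolerances

The randomized suites run, as the package's documented scales: 200 random
bidirected graphs of up to 50 nodes with up to 40 random threads each
(round trip, and 1000 count queries against brute force); 100 synthetic
variant-graph panels of 2–15 haplotypes over 40–100 bp references
(batch/incremental byte identity); panel duplication at k = 1, 2, 4, 8
(run-count constancy); and one 50-haplotype panel over a 1 kb reference
with 30 SNPs queried by 1000 random 100 bp walks (seed-reproducibility of
the count distribution). All comparisons on index content are exact
(`identical()` on integers and bytes); nothing in the package is compared
with floating-point tolerance. Every randomized test fixes its seeds, and
seeded runs are bit-reproducible across platforms because serialization
fixes endianness (little) and integer width (32-bit).

## Known limitations

* Rank is linear in the run count of one array; a succinct static
  structure would be needed for panels orders of magnitude larger.
* Construction and queries are single-threaded and in-memory.
* `batch_embed()` is limited to DAG-orientable graphs; cyclic graphs fall
  back to incremental embedding.
* The graph is immutable under an index; there is no incremental graph
  editing.
* VCF import handles substitutions and indels expressed as nonoverlapping
  replacements; symbolic alleles, breakends and overlapping records are
  rejected rather than normalized.
* The index file stores a checksum of the graph, not the graph; readers
  must supply the same graph (GFA round-trips are exact, so this is the
  natural pairing).
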