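# gpbwt

Haplotype panels stored against a **bidirected genome graph**, compressed and
searchable: an R implementation of the graph positional Burrows–Wheeler
transform (gPBWT).

## The problem

Reference-linear haplotype indexes (the PBWT and its descendants) assume that
every haplotype is a binary string over a totally ordered set of sites. Once
variation is represented as a *genome graph* — nodes carrying DNA labels, each
with a left (5′) and right (3′) *side*, and edges joining sides — a haplotype
becomes a walk that alternates crossing nodes and crossing edges, may start
and end anywhere, and may traverse structural variation in either direction.
This package stores a collection of such walks ("threads") so that

* the full collection can be reconstructed exactly from the index,
* the number of stored haplotypes containing any query path can be counted in
  time proportional to the query length (independent of the match count), and
* storage exploits linkage: haplotypes that locally agree occupy runs of
  identical entries, so additional samples cost little more than longer runs.

Typical users are people building graph-based read mappers, variant callers
or visualization tools who need "how many panel haplotypes are consistent
with this path?" as a primitive.

## The data structure

Node `k` has left side `2k−1` and right side `2k`; side `0` is the *null
side*, ordered before all real sides. A thread orientation is a side sequence
`[t0, t1, …, t(2N+1)]` with `t(2i)`, `t(2i+1)` opposite sides of one node and
`{t(2i+1), t(2i+2)}` an edge; a *thread* is the orientation pair considered as
one object (an ambisequence). For each side `s`, the index stores

* `B_s[]` — over all visits of stored orientations to `s`, sorted by their
  reversed histories, the side on which each visit enters its **next** node
  (null side = thread ends). Entries are kept as small local edge codes in
  run-length-compressed arrays with `O(log runs)` rank and insert.
* `c(x, s)` — for each oriented edge `(x, s)`, the smallest `B_s[]` index of a
  visit arriving through `{x, s}`, materialized as per-side start counts plus
  per-oriented-edge usage counts.

`where_to(s, i, s′) = c(opposite(s), s′) + rank_{s′}(B_s[], i)` plays the role
of the FM-index LF mapping: it carries a position in one B array to the
corresponding position in the next one. Embedding (`embed_thread`), exact
extraction (`extract_threads`), subthread counting (`count_subthread`) and
O(1)-extension streaming search (`extend_search`) are all built on it. For
graphs whose edges all run right-side-to-left-side acyclically,
`batch_embed()` builds the identical index without dynamic inserts by
merging pre-sorted visit lists side by side in topological order.

Around the core sit the supporting layers: graph construction from a
reference plus nonoverlapping variants (`graph_from_variants`) or GFA 1.0
(`read_gfa`/`write_gfa`), phased-VCF haplotype import with splitting of
invalid pieces (`import_phased_vcf`), synthetic mosaic haplotype panels and
random-walk queries (`simulate_haplotype_panel`, `random_walks`), and a CLI
(`run_cli`, wrapped by `inst/cli/gpbwt.R`).

## Worked example

The ten-side graph below (five nodes; edges `{2,5}`, `{4,5}`, `{6,7}`,
`{6,9}`, `{8,8}`, `{10,9}`) holds two threads, one of which loops through
node 5 twice and one of which crosses the self-loop on side 8:

```r
library(gpbwt)
g <- bidirected_graph(
  c("CAAATAAG", "A", "G", "T", "C"),
  rbind(c(2, 5), c(4, 5), c(6, 7), c(6, 9), c(8, 8), c(10, 9)))
idx <- gpbwt_index(g)
idx <- embed_thread(idx, c(1, 2, 5, 6, 9, 10, 9, 10))
idx <- embed_thread(idx, c(3, 4, 5, 6, 7, 8, 8, 7))

idx
#> gpbwt_index: 2 threads (4 orientations) over 5 nodes

b_array(idx, 5)          # next-visit sides for the two visits to side 5
#> [1] 9 7
c_value(idx, 4, 5)       # arrivals via {4,5} start at B_5[] index 1
#> [1] 1
count_subthread(idx, c(5, 6))         # both threads cross node 3
#> [1] 2
count_subthread(idx, c(5, 6, 9, 10))  # only one continues into node 5
#> [1] 1
gpbwt_stats(idx)
#> # A tibble: 1 × 5
#>   sides entries  runs bytes threads
#>   <int>   <int> <int> <int>   <int>
#> 1    10      16    15   316       2
```

`b_array(idx, 5)` reads: of the two thread orientations entering node 3
through side 5, the first (sorted by its reversed history — it arrived via
edge `{2,5}`) continues into side 9, the second (via `{4,5}`) into side 7.
`count_subthread` answers haplotype-consistency queries; a count of 0 means
no stored haplotype contains the path.

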