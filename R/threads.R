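# Threads: haplotypes (or fragments) as walks over graph sides.
#
# A thread orientation is an integer vector of sides of even length
# [t0, t1, ..., t(2N+1)]: t(2i) and t(2i+1) are the two sides of one node
# (the thread enters at t(2i), the "visit", and leaves by t(2i+1)), and
# consecutive node traversals are joined by edges {t(2i+1), t(2i+2)}. A
# thread proper is an ambisequence: an orientation and its reverse describe
# the same haplotype, and the canonical orientation is the lexicographically
# smaller of the two.

#' Reverse a thread orientation
#'
#' The two orientations of a thread are each other's reverses; a thread
#' itself, being an ambisequence, cannot be reversed.
#'
#' @param t integer vector of sides (a thread orientation).
#' @return The reversed orientation.
#' @examples
#' reverse_orientation(c(1, 2, 5, 6, 9, 10, 9, 10))
#' @export
reverse_orientation <- function(t) rev(as.integer(t))

#' Canonical orientation of a thread
#'
#' Of the two orientations of the underlying ambisequence, returns the
#' lexicographically smaller side sequence (a palindromic orientation is its
#' own canonical form). Canonicalization makes thread multisets comparable.
#'
#' @inheritParams reverse_orientation
#' @return The canonical orientation.
#' @export
canonical_orientation <- function(t) {
  t <- as.integer(t)
  r <- rev(t)
  d <- which(t != r)
  if (!length(d) || t[d[1L]] < r[d[1L]]) t else r
}

#' Validate a thread orientation against a graph
#'
#' Checks even length, that positions `2i` and `2i + 1` hold opposite sides
#' of one node, and that each consecutive node pair is joined by an edge.
#' Validation always returns (never throws), reporting the first violation.
#'
#' @param g a [bidirected_graph()].
#' @param t integer vector of sides.
#' @return A list with `ok` (logical) and, on failure, `at` (1-based
#'   position in `t` where the violation was detected) and `reason`.
#' @examples
#' g <- bidirected_graph(rep("A", 5),
#'   rbind(c(2, 5), c(4, 5), c(6, 7), c(6, 9), c(8, 8), c(10, 9)))
#' validate_thread(g, c(3, 4, 5, 6, 7, 8, 8, 7))$ok
#' @export
validate_thread <- function(g, t) {
  t <- as.integer(t)
  bad <- function(at, reason) list(ok = FALSE, at = at, reason = reason)
  if (!length(t)) return(bad(0L, "empty thread"))
  if (length(t) %% 2L != 0L) return(bad(length(t), "odd number of sides"))
  if (any(t < 1L)) return(bad(which(t < 1L)[1L], "null or negative side"))
  if (any(node_of(t) > length(g$labels)) || anyNA(g$labels[node_of(t)])) {
    at <- which(!has_node(g, node_of(t)))[1L]
    return(bad(at, sprintf("side %d belongs to no node in the graph", t[at])))
  }
  ev <- t[seq(1L, length(t), by = 2L)]
  od <- t[seq(2L, length(t), by = 2L)]
  w <- which(opposite(ev) != od)
  if (length(w)) {
    return(bad(2L * w[1L] - 1L,
               sprintf("sides %d and %d are not opposites", ev[w[1L]], od[w[1L]])))
  }
  if (length(ev) > 1L) {
    for (i in seq_len(length(ev) - 1L)) {
      if (!has_edge(g, od[i], ev[i + 1L])) {
        return(bad(2L * i, sprintf("no edge {%d, %d}", od[i], ev[i + 1L])))
      }
    }
  }
  list(ok = TRUE, at = NA_integer_, reason = NA_character_)
}

#' Thread visits
#'
#' The sides at even (0-based) positions of an orientation: one per arrival
#' of the thread at a node.
#'
#' @inheritParams reverse_orientation
#' @return Integer vector of entry sides.
#' @export
thread_visits <- function(t) {
  t <- as.integer(t)
  t[seq(1L, length(t), by = 2L)]
}

#' Convert between node paths and thread orientations
#'
#' A node path is a sequence of `(node, forward?)` traversals, the natural
#' reading of a GFA P line or of a mapped read's path. A forward traversal of
#' node `k` contributes sides `(2k - 1, 2k)`; a backward traversal
#' contributes `(2k, 2k - 1)`.
#'
#' @param g a [bidirected_graph()].
#' @param nodes integer vector of node identifiers.
#' @param forward logical vector, one flag per node (`TRUE` = forward).
#' @param t a thread orientation (for `thread_to_node_path`).
#' @return `thread_from_node_path()` returns a thread orientation;
#'   `thread_to_node_path()` a list with `nodes` and `forward`.
#' @examples
#' g <- bidirected_graph(rep("A", 5),
#'   rbind(c(2, 5), c(4, 5), c(6, 7), c(6, 9), c(8, 8), c(10, 9)))
#' thread_from_node_path(g, c(2, 3, 4), c(TRUE, TRUE, TRUE))  # 3 4 5 6 7 8
#' @export
thread_from_node_path <- function(g, nodes, forward = rep(TRUE, length(nodes))) {
  nodes <- as.integer(nodes)
  forward <- as.logical(forward)
  stopifnot(length(nodes) == length(forward), length(nodes) >= 1L)
  first <- ifelse(forward, left_side(nodes), right_side(nodes))
  t <- as.integer(rbind(first, opposite(first)))
  chk <- validate_thread(g, t)
  if (!chk$ok) stop("node path is not a walk in the graph: ", chk$reason,
                    call. = FALSE)
  t
}

#' @rdname thread_from_node_path
#' @export
thread_to_node_path <- function(t) {
  v <- thread_visits(t)
  list(nodes = node_of(v), forward = v %% 2L == 1L)
}

#' Oriented DNA sequence of a thread
#'
#' Concatenates the node labels along the orientation, reverse-complementing
#' labels of nodes entered through their right side.
#'
#' @param g a [bidirected_graph()].
#' @param t a thread orientation.
#' @return A single DNA string.
#' @export
thread_sequence <- function(g, t) {
  v <- thread_visits(t)
  pieces <- vapply(v, function(s) {
    lab <- node_label(g, node_of(s))
    if (s %% 2L == 1L) lab else revcomp(lab)
  }, character(1))
  paste(pieces, collapse = "")
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

# ---- Synthetic data: random walks -------------------------------------------

#' Simulate a random walk thread
#'
#' Starts at a uniformly chosen side, repeatedly crosses the node and then a
#' uniformly chosen edge incident on the exit side, and stops once the total
#' node-label length reaches `target_bp`. Reaching a dead end first yields a
#' failure value (`NULL`) so the caller can resample.
#'
#' @param g a nonempty [bidirected_graph()].
#' @param target_bp walk length to reach, in bases of node label.
#' @param seed optional integer seed; if `NULL` the current RNG state is used.
#' @return A thread orientation, or `NULL` if a dead end was reached.
#' @export
random_walk <- function(g, target_bp, seed = NULL) {
  if (!length(g$node_ids)) stop("graph is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  real_sides <- sort(c(left_side(g$node_ids), right_side(g$node_ids)))
  s <- real_sides[sample.int(length(real_sides), 1L)]
  t <- c(s, opposite(s))
  bp <- nchar(node_label(g, node_of(s)))
  while (bp < target_bp) {
    exits <- g$adj[[opposite(s)]]
    if (!length(exits)) return(NULL)
    s <- exits[sample.int(length(exits), 1L)]
    t <- c(t, s, opposite(s))
    bp <- bp + nchar(node_label(g, node_of(s)))
  }
  t
}

#' Simulate many random walks, resampling failures
#'
#' @inheritParams random_walk
#' @param n number of walks wanted.
#' @param max_retries resampling budget per walk before giving up.
#' @return A list of thread orientations (possibly shorter than `n` if the
#'   retry budget is exhausted), with attribute `n_failed`.
#' @export
random_walks <- function(g, n, target_bp, seed = NULL, max_retries = 20L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- vector("list", n)
  kept <- 0L; failed <- 0L
  for (k in seq_len(n)) {
    w <- NULL
    for (r in seq_len(max_retries)) {
      w <- random_walk(g, target_bp)
      if (!is.null(w)) break
    }
    if (is.null(w)) failed <- failed + 1L
    else { kept <- kept + 1L; out[[kept]] <- w }
  }
  out <- out[seq_len(kept)]
  attr(out, "n_failed") <- failed
  out
}

#' Drop walks crossing ambiguous sequence
#'
#' Removes walks whose oriented sequence contains `threshold` or more
#' consecutive `N` bases, the usual filter for walks wandering into
#' ambiguous regions of the reference.
#'
#' @param g a [bidirected_graph()].
#' @param walks list of thread orientations.
#' @param threshold run of `N`s (default 2) at which a walk is discarded.
#' @return The filtered list.
#' @export
drop_ambiguous_walks <- function(g, walks, threshold = 2L) {
  if (!length(walks)) return(walks)
  pat <- paste0("N{", as.integer(threshold), ",}")
  keep <- !vapply(walks, function(t) grepl(pat, thread_sequence(g, t)),
                  logical(1))
  walks[keep]
}

# ---- Synthetic data: correlated haplotype panels ----------------------------

#' Simulate a haplotype panel with linkage
#'
#' Generates haplotypes over the variants of a [graph_from_variants()] build
#' by a mosaic copying process: founders draw each variant allele
#' independently (reference or alternate with probability 1/2 each); each
#' subsequent haplotype copies a uniformly chosen earlier haplotype,
#' resampling its template with probability `switch_prob` at every variant
#' (recombination) and flipping the copied allele with probability
#' `flip_prob` (mutation). The copying process produces the long shared
#' allele runs -- linkage -- that make the index's B arrays compressible; it
#' is not a coalescent simulation.
#'
#' Requires one alternate allele per site (biallelic variants).
#'
#' @param build a `graph_build` from [graph_from_variants()].
#' @param n_haplotypes panel size.
#' @param n_founders number of independent founder haplotypes
#'   (`<= n_haplotypes`).
#' @param switch_prob per-variant template switch probability.
#' @param flip_prob per-variant allele flip probability.
#' @param seed optional integer seed.
#' @return A list of thread orientations, each traversing the graph left to
#'   right, with the 0/1 allele matrix attached as attribute `alleles`.
#' @export
simulate_haplotype_panel <- function(build, n_haplotypes, n_founders = 2L,
                                     switch_prob = 0.1, flip_prob = 0.01,
                                     seed = NULL) {
  stopifnot(inherits(build, "graph_build"),
            n_founders >= 1L, n_founders <= n_haplotypes,
            switch_prob >= 0, switch_prob <= 1,
            flip_prob >= 0, flip_prob <= 1)
  al <- build$alleles
  if (anyDuplicated(al$ref_start)) {
    stop("panel simulation requires biallelic sites (one alternate per site)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  nv <- nrow(al)
  ord <- order(al$ref_start)
  H <- matrix(0L, nrow = n_haplotypes, ncol = nv)
  for (h in seq_len(n_haplotypes)) {
    if (h <= n_founders) {
      H[h, ] <- stats::rbinom(nv, 1L, 0.5)
    } else {
      tmpl <- sample.int(h - 1L, 1L)
      for (j in ord) {
        if (stats::runif(1) < switch_prob) tmpl <- sample.int(h - 1L, 1L)
        a <- H[tmpl, j]
        if (stats::runif(1) < flip_prob) a <- 1L - a
        H[h, j] <- a
      }
    }
  }
  threads <- lapply(seq_len(n_haplotypes), function(h) {
    haplotype_thread(build, H[h, ])
  })
  attr(threads, "alleles") <- H
  threads
}

# thread orientation for one haplotype given its 0/1 allele vector (indexed
# as build$alleles rows); walks the reference backbone left to right,
# substituting alternate nodes where the allele says so
haplotype_thread <- function(build, alleles) {
  nodes <- build$backbone$node
  swap <- build$alleles$alt_node[alleles == 1L]
  names(swap) <- build$alleles$ref_node[alleles == 1L]
  hit <- match(as.character(nodes), names(swap))
  nodes[!is.na(hit)] <- swap[hit[!is.na(hit)]]
  thread_from_node_path(build$graph, nodes, rep(TRUE, length(nodes)))
}
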