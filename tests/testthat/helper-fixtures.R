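# Shared fixtures and independent oracles, all built in code.

# the ten-side worked-example graph used throughout: five single-base nodes, edges
# {2,5},{4,5},{6,7},{6,9},{8,8},{10,9}; labels are irrelevant to the index
tenside_graph <- function() {
  bidirected_graph(rep("A", 5),
                   rbind(c(2, 5), c(4, 5), c(6, 7), c(6, 9), c(8, 8),
                         c(10, 9)))
}

tenside_threads <- function() {
  list(c(1L, 2L, 5L, 6L, 9L, 10L, 9L, 10L),
       c(3L, 4L, 5L, 6L, 7L, 8L, 8L, 7L))
}

tenside_index <- function() {
  embed_threads(gpbwt_index(tenside_graph()), tenside_threads())
}

# random general bidirected graph (self-loops and left-left/right-right
# edges allowed), with occasional N bases in the labels
random_bidirected_graph <- function(max_nodes = 50L, with_n = FALSE) {
  n <- sample.int(max_nodes, 1L)
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  labels <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample.int(6L, 1L), replace = TRUE),
          collapse = "")
  }, character(1))
  n_edges <- sample.int(max(1L, 2L * n), 1L)
  sides <- 2L * n
  em <- cbind(sample.int(sides, n_edges, replace = TRUE),
              sample.int(sides, n_edges, replace = TRUE))
  em <- unique(cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L])))
  bidirected_graph(labels, em)
}

# random reference + nonoverlapping variants (SNPs and small indels), always
# DAG-orientable by construction
random_variant_build <- function(ref_len = 60L, n_variants = 6L) {
  ref <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
               collapse = "")
  starts <- sort(sample.int(ref_len - 2L, n_variants))
  keep <- c(TRUE, diff(starts) >= 2L)   # nonoverlapping 1bp ref alleles
  starts <- starts[keep]
  v <- data.frame(
    ref_start = starts,
    ref = vapply(starts, function(s) substr(ref, s + 1L, s + 1L),
                 character(1)),
    alt = vapply(starts, function(s) {
      base <- substr(ref, s + 1L, s + 1L)
      others <- setdiff(c("A", "C", "G", "T"), base)
      if (runif(1) < 0.7) sample(others, 1L)
      else paste(c(base, sample(others, sample.int(3L, 1L), replace = TRUE)),
                 collapse = "")  # insertion
    }, character(1))
  )
  graph_from_variants(ref, v)
}

# ---- definition-based oracle ------------------------------------------------
# Builds every B[] array and every c() value directly from the definition:
# collect all visits of the given orientations to each side, sort them by
# their reversed history (ties: later-embedded orientations first, matching
# the index's insertion-order tie-break), and read off each visit's
# next-visit side. Orientations must be given in embedding order.
naive_gpbwt <- function(g, orientations) {
  n_sides <- g$n_sides
  B <- rep(list(integer(0)), n_sides)
  starts <- integer(n_sides)
  arrivals <- lapply(seq_len(n_sides),
                     function(s) integer(length(g$adj[[s]])))
  for (s in seq_len(n_sides)) {
    keys <- character(0); ids <- integer(0); vals <- integer(0)
    first_prev <- integer(0)
    for (o in seq_along(orientations)) {
      t <- orientations[[o]]
      nv <- length(t) %/% 2L
      for (p in seq_len(nv)) {
        if (t[2L * p - 1L] != s) next
        prefix <- if (p > 1L) rev(t[seq_len(2L * p - 2L)]) else integer(0)
        keys <- c(keys, paste(sprintf("%06d", prefix), collapse = ","))
        ids <- c(ids, o)
        vals <- c(vals, if (p < nv) t[2L * p + 1L] else 0L)
        first_prev <- c(first_prev, if (p > 1L) prefix[1L] else 0L)
      }
    }
    if (length(keys)) {
      ord <- order(keys, -ids, method = "radix")
      B[[s]] <- vals[ord]
      starts[s] <- sum(keys == "")
      for (ai in seq_along(g$adj[[s]])) {
        arrivals[[s]][ai] <- sum(first_prev == g$adj[[s]][ai])
      }
    }
  }
  cfun <- function(x, s2) {
    k <- match(x, g$adj[[s2]])
    starts[s2] + if (k > 1L) sum(arrivals[[s2]][seq_len(k - 1L)]) else 0L
  }
  list(B = B, starts = starts, c = cfun)
}

# brute-force subthread occurrence count: scan both orientations of every
# embedded thread for the query as a contiguous run starting at a node
# boundary
brute_count <- function(threads, query) {
  query <- as.integer(query)
  total <- 0L
  for (t in threads) {
    for (o in list(as.integer(t), rev(as.integer(t)))) {
      if (length(query) > length(o)) next
      for (off in seq(1L, length(o) - length(query) + 1L, by = 2L)) {
        if (all(o[off:(off + length(query) - 1L)] == query)) {
          total <- total + 1L
        }
      }
    }
  }
  total
}

# multiset comparison of thread lists via canonical keys
thread_multiset <- function(threads) {
  sort(unname(vapply(threads, function(t) {
    paste(canonical_orientation(t), collapse = ",")
  }, character(1))))
}

# a small phased VCF written as plain text
write_toy_vcf <- function(path, records, samples) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(pos, ref, alt, gts) {
  paste(c("ref", pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
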