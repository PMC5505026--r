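test_that("side arithmetic follows the odd/even numbering convention", {
  expect_identical(opposite(5L), 6L)
  expect_identical(opposite(6L), 5L)
  expect_identical(node_of(9L), 5L)
  expect_identical(node_of(10L), 5L)
  expect_identical(node_of(1L), 1L)
  expect_identical(left_side(3L), 5L)
  expect_identical(right_side(3L), 6L)
  # involution without fixed points over a range of sides
  s <- 1:200
  expect_identical(opposite(opposite(s)), s)
  expect_true(all(opposite(s) != s))
  expect_identical(node_of(opposite(s)), node_of(s))
  # the null side belongs to no node
  expect_error(opposite(0L), "null side")
  expect_error(node_of(0L), "null side")
})

test_that("graph construction validates labels and edges", {
  g <- bidirected_graph(c("GAT", "T", "C", "ACA"),
                        rbind(c(2, 3), c(2, 5), c(6, 7), c(4, 7)))
  expect_identical(adjacent_sides(g, 7), c(4L, 6L))  # ascending side order
  expect_identical(adjacent_sides(g, 2), c(3L, 5L))
  expect_identical(adjacent_sides(g, 1), integer(0))
  expect_identical(node_label(g, 4), "ACA")
  expect_error(bidirected_graph(c("A", ""), NULL), "nonempty")
  expect_error(bidirected_graph("AXA", NULL), "DNA")
  expect_error(bidirected_graph("ACGT", rbind(c(1, 3))), "does not belong")
  expect_error(bidirected_graph(c("A", "C"), rbind(c(2, 3), c(3, 2))),
               "duplicate edge")
  # self-loops are single edges
  gl <- bidirected_graph("ACGT", rbind(c(2, 2)))
  expect_identical(adjacent_sides(gl, 2), 2L)
})

test_that("graph_from_variants applies the node-breaking recipe", {
  # single interior SNP
  b <- graph_from_variants("GATTACA",
                           data.frame(ref_start = 3, ref = "T", alt = "C"))
  g <- b$graph
  expect_identical(unname(g$labels), c("GAT", "T", "C", "ACA"))
  expect_identical(nrow(g$edges), 4L)
  expect_identical(adjacent_sides(g, 2), c(3L, 5L))
  expect_identical(adjacent_sides(g, 7), c(4L, 6L))
  expect_identical(b$alleles$ref_node, 2L)
  expect_identical(b$alleles$alt_node, 3L)
  expect_identical(b$backbone$node, c(1L, 2L, 4L))

  # no variants: one node, no edges
  b0 <- graph_from_variants("ACGT", NULL)
  expect_identical(length(b0$graph$node_ids), 1L)
  expect_identical(nrow(b0$graph$edges), 0L)

  # insertion allele
  bi <- graph_from_variants("ACGT",
                            data.frame(ref_start = 1, ref = "C", alt = "CTT"))
  expect_identical(unname(bi$graph$labels), c("A", "C", "CTT", "GT"))
  expect_identical(nrow(bi$graph$edges), 4L)

  # errors: overlap and ref mismatch
  expect_error(graph_from_variants("GATTACA", data.frame(
    ref_start = c(1, 2), ref = c("AT", "TT"), alt = c("C", "G"))),
    "overlapping")
  expect_error(graph_from_variants("GATTACA", data.frame(
    ref_start = 3, ref = "G", alt = "C")), "mismatch")
})

test_that("all-reference walk spells the reference; SNP node count is 3n+1", {
  set.seed(42)
  for (rep in 1:10) {
    ref_len <- sample(30:80, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
                 collapse = "")
    starts <- sort(sample(seq(2, ref_len - 3, by = 1), 4))
    starts <- starts[c(TRUE, diff(starts) >= 2)]  # interior, non-adjacent
    v <- data.frame(
      ref_start = starts,
      ref = vapply(starts, function(s) substr(ref, s + 1, s + 1),
                   character(1)),
      alt = "A"
    )
    v$alt <- vapply(v$ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    character(1))
    b <- graph_from_variants(ref, v)
    # reference reconstruction along the backbone
    expect_identical(
      paste(b$graph$labels[b$backbone$node], collapse = ""), ref)
    # n alt + n ref-allele + (n+1) flanking nodes
    n <- nrow(v)
    expect_identical(length(b$graph$node_ids), 3L * n + 1L)
  }
})

test_that("adjacent SNPs create no empty nodes and connect all allele pairs", {
  b <- graph_from_variants("GATG", data.frame(
    ref_start = c(1, 2), ref = c("A", "T"), alt = c("C", "G")))
  g <- b$graph
  # nodes: G, A, C, T, G(alt), G(tail) -- no empty segment between the SNPs
  expect_false(any(!nzchar(g$labels[g$node_ids])))
  expect_identical(length(g$node_ids), 6L)
  a1 <- b$alleles[b$alleles$ref_start == 1, ]
  a2 <- b$alleles[b$alleles$ref_start == 2, ]
  for (n1 in c(a1$ref_node, a1$alt_node)) {
    for (n2 in c(a2$ref_node, a2$alt_node)) {
      expect_true(right_side(n1) %in% adjacent_sides(g, left_side(n2)))
    }
  }
})

test_that("multiple alternates over one site share the reference node", {
  b <- graph_from_variants("GATTACA", data.frame(
    ref_start = c(3, 3), ref = c("T", "T"), alt = c("C", "G")))
  expect_identical(b$alleles$ref_node, c(2L, 2L))
  expect_identical(sort(b$alleles$alt_node), c(3L, 4L))
  expect_identical(length(b$graph$node_ids), 5L)
})

test_that("dag_orientation accepts variant graphs and rejects the loop graph", {
  b <- graph_from_variants("GATTACA",
                           data.frame(ref_start = 3, ref = "T", alt = "C"))
  d <- dag_orientation(b$graph)
  expect_true(d$success)
  expect_identical(d$order[1], 1L)          # GAT first
  expect_identical(d$order[4], 4L)          # ACA last
  expect_setequal(d$order[2:3], c(2L, 3L))  # T/C in either slot

  d2 <- dag_orientation(tenside_graph())
  expect_false(d2$success)
  expect_false(is.null(d2$edge))

  # empty graph: trivially orderable
  d0 <- dag_orientation(bidirected_graph(character(0), NULL))
  expect_true(d0$success)
  expect_identical(d0$order, integer(0))

  # right-left edges forming a directed cycle
  gc <- bidirected_graph(c("A", "C"), rbind(c(2, 3), c(4, 1)))
  dc <- dag_orientation(gc)
  expect_false(dc$success)
  expect_identical(dc$cycle, c(1L, 2L))
})

test_that("topological order puts every left-entry visit in increasing position", {
  set.seed(7)
  for (rep in 1:5) {
    b <- random_variant_build()
    d <- dag_orientation(b$graph)
    expect_true(d$success)
    pos <- match(b$backbone$node, d$order)
    expect_true(all(diff(pos) > 0))
    thr <- simulate_haplotype_panel(b, 3, seed = rep)
    for (t in thr) {
      vis <- thread_visits(t)
      expect_true(all(vis %% 2L == 1L))
      expect_true(all(diff(match(node_of(vis), d$order)) > 0))
    }
  }
})
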