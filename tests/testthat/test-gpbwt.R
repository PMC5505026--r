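# Core index behaviour. The worked ten-side example (tenside_* fixtures) pins
# down exact B[]/c() content; randomized cases are cross-checked against the
# definition-based oracle in helper-fixtures.R.

test_that("c(), start counts and where_to reproduce the worked example", {
  idx <- tenside_index()
  expect_identical(c_value(idx, 4, 5), 1L)
  expect_identical(c_value(idx, 6, 9), 0L)
  expect_identical(c_value(idx, 10, 9), 1L)
  expect_identical(c_value(idx, 2, 5), 0L)
  expect_identical(thread_starts(idx, 1), 1L)  # no incident edges: |B1|
  expect_identical(thread_starts(idx, 5), 0L)
  expect_identical(thread_starts(idx, 7), 1L)
  expect_identical(thread_starts(gpbwt_index(tenside_graph()), 3), 0L)
  expect_identical(where_to(idx, 5, 0, 9), 0L)
  expect_identical(where_to(idx, 9, 0, 9), 1L)
  expect_identical(where_to(idx, 5, 2, 7), 2L)
  expect_error(where_to(idx, 5, 0, 0), "null side")
  expect_error(c_value(idx, 2, 7), "no edge")
})

test_that("c() is monotone in the far endpoint", {
  set.seed(31)
  for (rep in 1:10) {
    g <- random_bidirected_graph(25L)
    walks <- random_walks(g, 8L, 15L, seed = rep)
    idx <- embed_threads(gpbwt_index(g), walks)
    for (s2 in seq_len(g$n_sides)) {
      adj <- adjacent_sides(g, s2)
      if (length(adj) > 1L) {
        cv <- vapply(adj, function(x) c_value(idx, x, s2), integer(1))
        expect_true(all(diff(cv) >= 0L))
      }
    }
  }
})

test_that("every visit is a start or an edge arrival (conservation)", {
  walks <- list()
  seed <- 13L
  while (length(walks) == 0L) {   # some random graphs are all dead ends
    seed <- seed + 1L
    set.seed(seed)
    g <- random_bidirected_graph(25L)
    walks <- random_walks(g, 10L, 15L, seed = seed)
  }
  expect_gt(length(walks), 0L)
  idx <- gpbwt_index(g)
  for (t in walks) {
    idx <- embed_thread(idx, t)
    for (s in seq_len(g$n_sides)) {
      expect_identical(length(idx$B[[s]]),
                       idx$starts[s] + sum(idx$uses[[s]]))
    }
  }
})

test_that("single-thread embedding matches the definition-based oracle", {
  set.seed(17)
  for (rep in 1:15) {
    g <- random_bidirected_graph(20L)
    walks <- random_walks(g, sample.int(8L, 1), 12L, seed = 1000L + rep)
    idx <- embed_threads(gpbwt_index(g), walks)
    # orientations in embedding order: canonical then reverse per thread
    ors <- list()
    for (t in walks) {
      can <- canonical_orientation(t)
      ors <- c(ors, list(can, rev(can)))
    }
    oracle <- naive_gpbwt(g, ors)
    for (s in seq_len(g$n_sides)) {
      expect_identical(b_array(idx, s), oracle$B[[s]])
      expect_identical(idx$starts[s], oracle$starts[s])
      for (x in adjacent_sides(g, s)) {
        expect_identical(c_value(idx, x, s), oracle$c(x, s))
      }
    }
  }
})

test_that("embedding a single short thread populates only its start side", {
  g <- tenside_graph()
  idx <- embed_orientation(gpbwt_index(g), c(1, 2))
  expect_identical(b_array(idx, 1), 0L)
  for (s in 2:10) expect_identical(length(idx$B[[s]]), 0L)
  expect_identical(idx$n_orientations, 1L)
  # invalid thread leaves the index unchanged
  expect_error(embed_orientation(idx, c(1, 2, 7, 8)), "invalid thread")
  expect_identical(idx$n_orientations, 1L)
})

test_that("re-embedding an orientation doubles run lengths, not run counts", {
  g <- tenside_graph()
  t <- c(1L, 2L, 5L, 6L, 9L, 10L, 9L, 10L)
  once <- embed_orientation(gpbwt_index(g), t)
  twice <- embed_orientation(once, t)
  for (s in seq_len(g$n_sides)) {
    expect_identical(rla_run_count(twice$B[[s]]), rla_run_count(once$B[[s]]))
    expect_identical(length(twice$B[[s]]), 2L * length(once$B[[s]]))
  }
})

test_that("extraction inverts embedding", {
  # worked example: exactly the four orientations of the two threads
  idx <- tenside_index()
  ors <- extract_orientations(idx)
  expect_identical(length(ors), 4L)
  expected <- unlist(lapply(tenside_threads(), function(t) {
    list(t, rev(t))
  }), recursive = FALSE)
  expect_identical(sort(vapply(ors, paste, character(1), collapse = ",")),
                   sort(vapply(expected, paste, character(1), collapse = ",")))
  thr <- extract_threads(idx)
  expect_identical(thr$n, c(1L, 1L))
  expect_identical(thread_multiset(thr$thread),
                   thread_multiset(tenside_threads()))
  # empty index extracts nothing
  expect_identical(extract_orientations(gpbwt_index(tenside_graph())), list())
  # a duplicated thread comes back with multiplicity two
  dup <- embed_threads(gpbwt_index(tenside_graph()),
                       list(c(1, 2, 5, 6), c(1, 2, 5, 6)))
  thr2 <- extract_threads(dup)
  expect_identical(thr2$n, 2L)
})

test_that("round trip holds on random graphs and random walks", {
  set.seed(23)
  for (rep in 1:10) {
    g <- random_bidirected_graph(30L)
    walks <- random_walks(g, sample.int(12L, 1), 15L, seed = 2000L + rep)
    idx <- embed_threads(gpbwt_index(g), walks)
    thr <- extract_threads(idx)
    got <- rep(thr$thread, thr$n)
    expect_identical(thread_multiset(got), thread_multiset(walks))
  }
})

test_that("subthread counts match the worked example and brute force", {
  idx <- tenside_index()
  expect_identical(count_subthread(idx, c(5, 6)), 2L)
  expect_identical(count_subthread(idx, c(5, 6, 9, 10)), 1L)
  expect_identical(count_subthread(idx, c(1, 2, 7, 8)), 0L)
  # single-node query counts all visits through that side
  expect_identical(count_subthread(idx, c(9, 10)), 2L)
  # the self-loop edge {8,8} is navigable
  expect_identical(count_subthread(idx, c(7, 8, 8, 7)), 2L)
  expect_identical(count_subthread(idx, c(3, 4, 5, 6, 7, 8, 8, 7)), 1L)
  # malformed structure errors; absent edges return 0
  expect_error(count_subthread(idx, c(1, 3)), "opposite")
  expect_error(count_subthread(idx, c(1, 2, 5)), "even-length")
})

test_that("count equals brute force and is orientation-symmetric", {
  set.seed(41)
  for (rep in 1:8) {
    g <- random_bidirected_graph(25L)
    walks <- random_walks(g, 10L, 15L, seed = 3000L + rep)
    idx <- embed_threads(gpbwt_index(g), walks)
    ors <- extract_orientations(idx)
    for (q in 1:12) {
      # random query: subpath of a stored orientation, or a fresh walk
      if (length(ors) && runif(1) < 0.7) {
        o <- ors[[sample.int(length(ors), 1L)]]
        nv <- length(o) %/% 2L
        a <- sample.int(nv, 1L)
        b <- a + sample.int(nv - a + 1L, 1L) - 1L
        qy <- o[(2L * a - 1L):(2L * b)]
      } else {
        qy <- random_walk(g, 8L)
        if (is.null(qy)) next
      }
      expected <- brute_count(walks, qy)
      expect_identical(count_subthread(idx, qy), expected)
      expect_identical(count_subthread(idx, rev(qy)), expected)
    }
  }
})

test_that("incremental search ranges narrow monotonically", {
  idx <- tenside_index()
  r <- search_start(idx, 5)
  expect_identical(c(r$f, r$g), c(0L, 2L))
  r2 <- extend_search(idx, r, 9)
  expect_identical(c(r2$side, r2$f, r2$g), c(9L, 0L, 1L))
  # extending an empty range stays empty
  r0 <- extend_search(idx, structure(list(side = 5L, f = 1L, g = 1L),
                                     class = "gpbwt_range"), 9)
  expect_identical(r0$f, r0$g)
  # extending across a missing edge empties the range
  r3 <- extend_search(idx, search_start(idx, 1), 7)
  expect_identical(r3$f, r3$g)
  # stepwise ranges reproduce count_subthread and never widen
  set.seed(53)
  g <- random_bidirected_graph(20L)
  walks <- random_walks(g, 8L, 15L, seed = 53)
  jdx <- embed_threads(gpbwt_index(g), walks)
  for (t in walks) {
    vis <- thread_visits(t)
    r <- search_start(jdx, vis[1])
    widths <- r$g - r$f
    for (v in vis[-1]) {
      r <- extend_search(jdx, r, v)
      widths <- c(widths, r$g - r$f)
    }
    expect_true(all(diff(widths) <= 0L))
    expect_identical(widths[length(widths)], count_subthread(jdx, t))
  }
})

test_that("index serialization round-trips and is guarded", {
  set.seed(61)
  g <- random_bidirected_graph(20L)
  walks <- random_walks(g, 6L, 12L, seed = 61)
  idx <- embed_threads(gpbwt_index(g), walks)
  path <- withr::local_tempfile(fileext = ".gpbwt")
  gpbwt_write(idx, path)
  back <- gpbwt_read(path, g)
  expect_identical(idx, back)
  expect_identical(gpbwt_serialize(back), gpbwt_serialize(idx))
  # wrong graph is refused
  g2 <- random_bidirected_graph(20L)
  expect_error(gpbwt_read(path, g2), "checksum|side count|adjacency")
  # stats reflect content
  st <- gpbwt_stats(idx)
  expect_identical(st$threads, length(walks))
  expect_identical(st$entries, sum(vapply(idx$B, length, integer(1))))
  st0 <- gpbwt_stats(gpbwt_index(g))
  expect_identical(st0$threads, 0L)
})
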