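# The gPBWT proper: per-side B[] arrays plus the counts realizing the c()
# function, with LF-mapping-style navigation (where_to), incremental
# embedding, exact extraction, and subthread occurrence counting.
#
# For a side s, B[s] lists, over all visits of embedded thread orientations
# to s (sorted by their reversed history, ties by reverse insertion order),
# the side on which each visit enters its *next* node, or the null side if
# the thread ends. Entries are stored not as raw side ids but as small local
# codes: code k >= 1 means the k-th side reachable by one edge hop from
# opposite(s) (in ascending side order), and code 0 is the null side. c(x, s')
# is the smallest index in B[s'] of a visit arriving through edge {x, s'};
# it is materialized as a per-side start count plus per-oriented-edge usage
# counts, from which any c value is a prefix sum.

#' Create an empty gPBWT index over a graph
#'
#' @param graph a [bidirected_graph()]. The graph is treated as immutable
#'   once an index exists over it: B[] order and c() validity depend on its
#'   adjacency order.
#' @return An object of class `gpbwt_index` with no embedded threads.
#' @examples
#' g <- bidirected_graph(rep("A", 5),
#'   rbind(c(2, 5), c(4, 5), c(6, 7), c(6, 9), c(8, 8), c(10, 9)))
#' idx <- gpbwt_index(g)
#' idx <- embed_thread(idx, c(1, 2, 5, 6, 9, 10, 9, 10))
#' idx <- embed_thread(idx, c(3, 4, 5, 6, 7, 8, 8, 7))
#' b_array(idx, 5)          # 9 7
#' count_subthread(idx, c(5, 6, 9, 10))  # 1
#' @export
gpbwt_index <- function(graph) {
  stopifnot(inherits(graph, "bidirected_graph"))
  n <- graph$n_sides
  structure(
    list(
      graph = graph,
      B = replicate(n, rle_array(), simplify = FALSE),
      starts = integer(n),
      uses = lapply(graph$adj, function(a) integer(length(a))),
      n_orientations = 0L
    ),
    class = "gpbwt_index"
  )
}

#' @export
print.gpbwt_index <- function(x, ...) {
  cat("gpbwt_index: ", x$n_orientations %/% 2L, " threads (",
      x$n_orientations, " orientations) over ",
      length(x$graph$node_ids), " nodes\n", sep = "")
  invisible(x)
}

# local-alphabet codec: the alphabet of B[s] is the list of sides reachable
# in one edge hop from opposite(s), ascending
side_code <- function(g, s, s_next) {
  if (s_next == 0L) return(0L)
  k <- match(s_next, g$adj[[opposite(s)]])
  if (is.na(k)) {
    stop("no edge {", opposite(s), ", ", s_next, "} in the graph",
         call. = FALSE)
  }
  k
}

side_decode <- function(g, s, code) {
  if (code == 0L) return(0L)
  alpha <- g$adj[[opposite(s)]]
  if (code > length(alpha)) {
    stop("corrupt index: code ", code, " exceeds the local alphabet of side ",
         s, call. = FALSE)
  }
  alpha[code]
}

#' Decoded B array of a side
#'
#' The B array of side `s` as side identifiers (0 for the thread-terminating
#' null side), one entry per visit in reverse-history sorted order.
#'
#' @param idx a [gpbwt_index()].
#' @param s a real side.
#' @return Integer vector of next-visit sides.
#' @export
b_array <- function(idx, s) {
  codes <- as.integer(idx$B[[s]])
  vapply(codes, function(cd) side_decode(idx$graph, s, cd), integer(1))
}

#' The c() function of the index
#'
#' For an oriented edge `(x, s2)`, the smallest index in `B[s2]` of a visit
#' arriving through edge `{x, s2}` (equivalently, where such a visit would be
#' inserted if none exists): the count of starting threads at `s2` plus the
#' usage counts of all edges whose far endpoint precedes `x` in side order.
#'
#' @param idx a [gpbwt_index()].
#' @param x,s2 sides joined by an edge.
#' @return A 0-based index into `B[s2]`.
#' @export
c_value <- function(idx, x, s2) {
  adj <- idx$graph$adj[[s2]]
  k <- match(x, adj)
  if (is.na(k)) {
    stop("no edge {", x, ", ", s2, "} in the graph", call. = FALSE)
  }
  idx$starts[s2] + if (k > 1L) sum(idx$uses[[s2]][seq_len(k - 1L)]) else 0L
}

#' Number of thread orientations beginning at a side
#'
#' The minimum of `c(x, s)` over sides `x` adjacent to `s`, or the length of
#' `B[s]` when `s` has no incident edges: starting visits occupy the lowest
#' indexes of `B[s]` because their (empty) history sorts before every other.
#'
#' @param idx a [gpbwt_index()].
#' @param s a real side.
#' @return Count of orientations starting at `s`.
#' @export
thread_starts <- function(idx, s) {
  adj <- idx$graph$adj[[s]]
  if (!length(adj)) return(length(idx$B[[s]]))
  min(vapply(adj, function(x) c_value(idx, x, s), integer(1)))
}

#' LF-style mapping between B arrays
#'
#' Given a visit of side `s` holding index `i` in `B[s]` and heading for side
#' `s2` next, returns the corresponding index in `B[s2]`:
#' `c(opposite(s), s2)` plus the number of entries before `i` in `B[s]` equal
#' to `s2`. Extraction passes the decoded B entry as `s2`; counting passes
#' the query's next visit.
#'
#' @param idx a [gpbwt_index()].
#' @param s current entry side.
#' @param i 0-based index into `B[s]` (may equal its length, for ranges).
#' @param s2 next entry side; must be joined to `opposite(s)` by an edge and
#'   may not be the null side.
#' @return A 0-based index into `B[s2]`.
#' @export
where_to <- function(idx, s, i, s2) {
  if (s2 == 0L) stop("the null side has no continuation", call. = FALSE)
  code <- side_code(idx$graph, s, s2)
  c_value(idx, opposite(s), s2) + rla_rank_before(idx$B[[s]], code, i)
}

# ---- Embedding --------------------------------------------------------------

#' Embed a thread orientation or thread into the index
#'
#' `embed_orientation()` inserts one directed reading of a thread:
#' the start entry goes to position 0 of its first side's B array (newly
#' added orientations sort, among equal histories, before previously added
#' ones), and each subsequent visit's entry is placed at the position the
#' LF mapping dictates, keeping every B array sorted by reversed history.
#' Edge usage and start counts -- the materialization of c() -- are updated as
#' entries are inserted. `embed_thread()` embeds both orientations of a
#' thread, canonical first; `embed_threads()` embeds a list of threads in
#' order.
#'
#' An invalid thread raises an error before any modification.
#'
#' @param idx a [gpbwt_index()].
#' @param t a thread orientation validating against the index's graph.
#' @param threads a list of thread orientations (each taken as a thread).
#' @return The updated index.
#' @export
embed_orientation <- function(idx, t) {
  t <- as.integer(t)
  chk <- validate_thread(idx$graph, t)
  if (!chk$ok) {
    stop("invalid thread at position ", chk$at, ": ", chk$reason,
         call. = FALSE)
  }
  g <- idx$graph
  vis <- thread_visits(t)
  nv <- length(vis)
  s0 <- vis[1L]
  code0 <- if (nv > 1L) side_code(g, s0, vis[2L]) else 0L
  idx$B[[s0]] <- rla_insert_at(idx$B[[s0]], 0L, code0)
  idx$starts[s0] <- idx$starts[s0] + 1L
  k <- 0L
  if (nv > 1L) {
    for (i in seq_len(nv - 1L)) {
      sp <- vis[i + 1L]
      x <- opposite(vis[i])           # arrival is via oriented edge (x, sp)
      ai <- match(x, g$adj[[sp]])
      idx$uses[[sp]][ai] <- idx$uses[[sp]][ai] + 1L
      k <- where_to(idx, vis[i], k, sp)
      code <- if (i + 1L < nv) side_code(g, sp, vis[i + 2L]) else 0L
      idx$B[[sp]] <- rla_insert_at(idx$B[[sp]], k, code)
    }
  }
  idx$n_orientations <- idx$n_orientations + 1L
  idx
}

#' @rdname embed_orientation
#' @export
embed_thread <- function(idx, t) {
  can <- canonical_orientation(t)
  idx <- embed_orientation(idx, can)
  embed_orientation(idx, reverse_orientation(can))
}

#' @rdname embed_orientation
#' @export
embed_threads <- function(idx, threads) {
  for (t in threads) idx <- embed_thread(idx, t)
  idx
}

# ---- Extraction -------------------------------------------------------------

#' Extract all embedded thread orientations
#'
#' Reproduces the stored orientations from the index alone: for each side
#' and each starting slot, follows B entries through the LF mapping until
#' the null side. Yields exactly as many orientations as were embedded
#' (each thread contributes two).
#'
#' @param idx a [gpbwt_index()].
#' @return A list of thread orientations.
#' @export
extract_orientations <- function(idx) {
  out <- vector("list", idx$n_orientations)
  k <- 0L
  for (s in seq_len(idx$graph$n_sides)) {
    b <- thread_starts(idx, s)
    if (b > 0L) {
      for (i in seq_len(b) - 1L) {
        k <- k + 1L
        if (k > idx$n_orientations) {
          stop("corrupt index: more starting orientations than embedded",
               call. = FALSE)
        }
        out[[k]] <- trace_orientation(idx, s, i)
      }
    }
  }
  if (k != idx$n_orientations) {
    stop("corrupt index: expected ", idx$n_orientations,
         " orientations, traced ", k, call. = FALSE)
  }
  out
}

trace_orientation <- function(idx, s, i) {
  g <- idx$graph
  t <- c(s, opposite(s))
  repeat {
    code <- rla_value_at(idx$B[[s]], i)
    if (code == 0L) return(t)
    sp <- side_decode(g, s, code)
    i2 <- where_to(idx, s, i, sp)
    if (i2 >= length(idx$B[[sp]])) {
      stop("corrupt index: dangling continuation from side ", s,
           " entry ", i, call. = FALSE)
    }
    t <- c(t, sp, opposite(sp))
    s <- sp
    i <- i2
  }
}

#' Extract the embedded thread multiset
#'
#' Canonicalizes every extracted orientation; each thread's two orientations
#' collapse to one canonical form, so every canonical form must appear an
#' even number of times (odd multiplicity indicates corruption). Returns
#' each distinct thread with its multiplicity halved.
#'
#' @param idx a [gpbwt_index()].
#' @return A tibble with list-column `thread` (canonical orientations) and
#'   integer `n` (multiplicity), ordered deterministically.
#' @export
extract_threads <- function(idx) {
  ors <- extract_orientations(idx)
  if (!length(ors)) {
    return(tibble::tibble(thread = list(), n = integer(0)))
  }
  cans <- lapply(ors, canonical_orientation)
  keys <- vapply(cans, paste, character(1), collapse = ",")
  tab <- table(keys)
  if (any(tab %% 2L != 0L)) {
    stop("corrupt index: thread ", names(tab)[tab %% 2L != 0L][1L],
         " extracted with odd multiplicity", call. = FALSE)
  }
  u <- !duplicated(keys)
  ord <- order(keys[u], method = "radix")
  tibble::tibble(
    thread = cans[u][ord],
    n = as.integer(tab[keys[u][ord]] %/% 2L)
  )
}

# ---- Counting ---------------------------------------------------------------

#' Count occurrences of a subthread
#'
#' Counts how many times the query orientation `t` occurs as a contiguous
#' subthread of the embedded threads, by backward-search-style range
#' narrowing: the initial range spans all of `B[t[1]]`, and each subsequent
#' visit maps both endpoints through the LF mapping. Because both
#' orientations of every thread are embedded, a query and its reverse return
#' the same count. A query using a side pair not joined by any edge returns
#' 0 (it is consistent with no haplotype) rather than erroring; a
#' structurally malformed query (odd length, non-opposite node pair) errors.
#'
#' @param idx a [gpbwt_index()].
#' @param t a thread orientation to search for.
#' @return Number of occurrences (0 or more).
#' @export
count_subthread <- function(idx, t) {
  r <- search_range(idx, t)
  if (is.null(r)) 0L else max(0L, r$g - r$f)
}

search_range <- function(idx, t) {
  t <- as.integer(t)
  if (!length(t) || length(t) %% 2L != 0L) {
    stop("query must be a nonempty even-length side sequence", call. = FALSE)
  }
  vis <- t[seq(1L, length(t), by = 2L)]
  ex <- t[seq(2L, length(t), by = 2L)]
  if (any(t < 1L)) stop("query contains the null side", call. = FALSE)
  if (any(opposite(vis) != ex)) {
    stop("query positions 2i and 2i+1 must be opposite sides", call. = FALSE)
  }
  if (any(!has_node(idx$graph, node_of(vis)))) return(NULL)
  r <- search_start(idx, vis[1L])
  if (length(vis) > 1L) {
    for (i in 2L:length(vis)) {
      r <- extend_search(idx, r, vis[i])
      if (r$f >= r$g) return(r)
    }
  }
  r
}

#' Incremental subthread search ranges
#'
#' `search_start()` opens a range over all visits to a side;
#' `extend_search()` performs one step of the counting recurrence, narrowing
#' the range to orientations whose next visit enters `next_visit`. Ranges
#' are half-open `[f, g)` into the B array of `side`; an empty range stays
#' empty, and extending across a nonexistent edge empties the range. This
#' supports streaming queries: a longer query beginning with an
#' already-searched prefix continues from the prefix's range.
#'
#' @param idx a [gpbwt_index()].
#' @param s side opening the search.
#' @param r a `gpbwt_range`.
#' @param next_visit entry side of the query's next node.
#' @return A `gpbwt_range`: list with `side`, `f`, `g`.
#' @export
search_start <- function(idx, s) {
  structure(list(side = as.integer(s), f = 0L, g = length(idx$B[[s]])),
            class = "gpbwt_range")
}

#' @rdname search_start
#' @export
extend_search <- function(idx, r, next_visit) {
  next_visit <- as.integer(next_visit)
  empty <- structure(list(side = next_visit, f = 0L, g = 0L),
                     class = "gpbwt_range")
  if (r$f >= r$g) return(empty)
  if (!has_edge(idx$graph, opposite(r$side), next_visit)) return(empty)
  structure(
    list(side = next_visit,
         f = where_to(idx, r$side, r$f, next_visit),
         g = where_to(idx, r$side, r$g, next_visit)),
    class = "gpbwt_range"
  )
}

#' @export
print.gpbwt_range <- function(x, ...) {
  cat("gpbwt_range: side ", x$side, ", [", x$f, ", ", x$g, ")\n", sep = "")
  invisible(x)
}

# ---- Serialization ----------------------------------------------------------

# polynomial checksum over a canonical rendering of the graph, mod 2^31 - 1;
# used to refuse loading an index against the wrong graph
graph_checksum <- function(g) {
  txt <- paste(c(length(g$node_ids), g$labels[g$node_ids],
                 t(g$edges)), collapse = "|")
  bytes <- utf8ToInt(txt)
  h <- 0
  p <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% p
  as.integer(h)
}

GPBWT_MAGIC <- c(71L, 80L, 66L, 87L)  # "GPBW"
GPBWT_VERSION <- 1L

#' Serialize and deserialize a gPBWT index
#'
#' The envelope is versioned and fixed-layout (little-endian 32-bit
#' integers): magic, version, a checksum of the graph, the per-side start
#' counts, per-oriented-edge usage counts, and each side's run-length
#' compressed B array in canonical (maximal-run) form, so equal indexes
#' serialize byte-identically across platforms. The graph itself is not
#' stored; `gpbwt_read()` takes it as an argument and refuses a mismatched
#' graph.
#'
#' @param idx a [gpbwt_index()].
#' @param path file to write or read.
#' @param graph the [bidirected_graph()] the index was built over.
#' @return `gpbwt_serialize()` returns a raw vector; `gpbwt_write()` is
#'   called for its side effect; `gpbwt_read()` and `gpbwt_deserialize()`
#'   return the index.
#' @export
gpbwt_serialize <- function(idx) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wi(GPBWT_MAGIC)
  wi(GPBWT_VERSION)
  wi(graph_checksum(idx$graph))
  wi(idx$graph$n_sides)
  wi(idx$n_orientations)
  wi(idx$starts)
  for (s in seq_len(idx$graph$n_sides)) {
    wi(length(idx$uses[[s]]))
    if (length(idx$uses[[s]])) wi(idx$uses[[s]])
    rla_write(idx$B[[s]], con)
  }
  rawConnectionValue(con)
}

#' @rdname gpbwt_serialize
#' @export
gpbwt_write <- function(idx, path) {
  writeBin(gpbwt_serialize(idx), path)
  invisible(path)
}

#' @rdname gpbwt_serialize
#' @export
gpbwt_deserialize <- function(raw_bytes, graph) {
  con <- rawConnection(raw_bytes, "rb")
  on.exit(close(con))
  read_gpbwt_con(con, graph)
}

#' @rdname gpbwt_serialize
#' @export
gpbwt_read <- function(path, graph) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_gpbwt_con(con, graph)
}

read_gpbwt_con <- function(con, graph) {
  ri <- function(n) {
    x <- readBin(con, "integer", n = n, size = 4L, endian = "little")
    if (length(x) != n) stop("truncated gPBWT index file", call. = FALSE)
    x
  }
  if (!identical(ri(4L), GPBWT_MAGIC)) {
    stop("not a gPBWT index file", call. = FALSE)
  }
  ver <- ri(1L)
  if (ver != GPBWT_VERSION) {
    stop("unsupported gPBWT index version ", ver, call. = FALSE)
  }
  ck <- ri(1L)
  if (ck != graph_checksum(graph)) {
    stop("index was not built over this graph (checksum mismatch)",
         call. = FALSE)
  }
  n_sides <- ri(1L)
  if (n_sides != graph$n_sides) {
    stop("index side count does not match the graph", call. = FALSE)
  }
  n_or <- ri(1L)
  idx <- gpbwt_index(graph)
  idx$n_orientations <- n_or
  idx$starts <- ri(n_sides)
  for (s in seq_len(n_sides)) {
    nu <- ri(1L)
    if (nu != length(graph$adj[[s]])) {
      stop("index adjacency does not match the graph at side ", s,
           call. = FALSE)
    }
    idx$uses[[s]] <- if (nu) ri(nu) else integer(0)
    idx$B[[s]] <- rla_read(con)
  }
  idx
}

#' Index summary statistics
#'
#' @param idx a [gpbwt_index()].
#' @return A one-row tibble: sides, total B entries, total runs, serialized
#'   bytes, embedded threads.
#' @export
gpbwt_stats <- function(idx) {
  tibble::tibble(
    sides = idx$graph$n_sides,
    entries = sum(vapply(idx$B, length, integer(1))),
    runs = sum(vapply(idx$B, rla_run_count, integer(1))),
    bytes = length(gpbwt_serialize(idx)),
    threads = idx$n_orientations %/% 2L
  )
}
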