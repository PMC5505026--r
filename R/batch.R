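# Batch gPBWT construction for DAG-orientable graphs.
#
# When every edge joins the right side of one node to the left side of
# another and the induced directed graph is acyclic, forward orientations
# enter nodes only on left sides and reverse orientations only on right
# sides, and each orientation visits a side at most once. The B arrays can
# then be produced side by side, in topological order, without a dynamic
# insert: each side's visit order is the concatenation of its newly starting
# orientations (ordered as the incremental algorithm would order them)
# followed by one pre-sorted arrival list per incident edge in adjacency
# order; the visits are then stably partitioned by next side into the
# outgoing lists consumed downstream.

#' Batch-build a gPBWT index on a DAG-orientable graph
#'
#' Produces exactly the index (B arrays, start counts, edge usage counts --
#' and therefore the identical serialized bytes) that [embed_thread()] would
#' produce for the same thread list in the same order, without any dynamic
#' array insertion. Requires [dag_orientation()] to succeed and every thread
#' to traverse nodes left to right in its forward orientation, which is
#' automatic on such graphs.
#'
#' Forward orientations are processed over left sides in topological order,
#' then reverse orientations over right sides in reverse topological order.
#'
#' @param g a [bidirected_graph()] for which [dag_orientation()] succeeds.
#' @param threads list of thread orientations, each taken as a thread (both
#'   orientations are indexed).
#' @return A [gpbwt_index()].
#' @examples
#' b <- graph_from_variants("GATTACA",
#'                          data.frame(ref_start = 3, ref = "T", alt = "C"))
#' thr <- list(thread_from_node_path(b$graph, c(1, 2, 4)),
#'             thread_from_node_path(b$graph, c(1, 3, 4)))
#' idx <- batch_embed(b$graph, thr)
#' identical(gpbwt_serialize(idx),
#'           gpbwt_serialize(embed_threads(gpbwt_index(b$graph), thr)))
#' @export
batch_embed <- function(g, threads) {
  d <- dag_orientation(g)
  if (!d$success) {
    stop("graph is not DAG-orientable (", d$reason,
         "); use embed_thread() for incremental construction",
         call. = FALSE)
  }
  m <- length(threads)
  fwd <- vector("list", m)
  fwd_id <- integer(m)
  rev_id <- integer(m)
  for (j in seq_len(m)) {
    t <- as.integer(threads[[j]])
    chk <- validate_thread(g, t)
    if (!chk$ok) {
      stop("invalid thread ", j, " at position ", chk$at, ": ", chk$reason,
           call. = FALSE)
    }
    can <- canonical_orientation(t)
    f <- if (can[1L] %% 2L == 1L) can else rev(can)
    if (any(thread_visits(f) %% 2L == 0L)) {
      stop("thread ", j, " does not traverse nodes left to right",
           call. = FALSE)
    }
    fwd[[j]] <- f
    # the incremental path embeds canonical then reverse; among equal
    # histories later insertions sort first, so these positions are the
    # tie-break keys
    if (identical(f, can)) {
      fwd_id[j] <- 2L * j - 1L; rev_id[j] <- 2L * j
    } else {
      fwd_id[j] <- 2L * j; rev_id[j] <- 2L * j - 1L
    }
  }

  idx <- gpbwt_index(g)
  idx <- batch_pass(idx, fwd, fwd_id, d$order, left = TRUE)
  idx <- batch_pass(idx, lapply(fwd, rev), rev_id, rev(d$order), left = FALSE)
  idx$n_orientations <- 2L * m
  idx
}

# one sweep: embed the given orientations over the entry sides they use
# (left sides for forward orientations, right sides for reverse), visiting
# nodes in the given order so arrival lists are ready when needed
batch_pass <- function(idx, orients, ids, node_seq, left) {
  g <- idx$graph
  vis <- lapply(orients, thread_visits)
  first_side <- vapply(vis, function(v) v[1L], integer(1))
  queues <- new.env(parent = emptyenv())

  for (node in node_seq) {
    s <- if (left) left_side(node) else right_side(node)
    adj <- g$adj[[s]]

    st <- which(first_side == s)
    st <- st[order(ids[st], decreasing = TRUE)]
    recs_o <- st
    recs_p <- rep(1L, length(st))
    uses_vec <- integer(length(adj))
    for (ai in seq_along(adj)) {
      ql <- queues[[paste0(adj[ai], "|", s)]]
      if (!is.null(ql)) {
        recs_o <- c(recs_o, ql$o)
        recs_p <- c(recs_p, ql$p)
        uses_vec[ai] <- length(ql$o)
      }
    }
    idx$starts[s] <- length(st)
    idx$uses[[s]] <- uses_vec
    if (!length(recs_o)) next

    alpha <- g$adj[[opposite(s)]]
    nxt <- integer(length(recs_o))
    codes <- integer(length(recs_o))
    for (r in seq_along(recs_o)) {
      v <- vis[[recs_o[r]]]
      if (recs_p[r] < length(v)) {
        nxt[r] <- v[recs_p[r] + 1L]
        codes[r] <- match(nxt[r], alpha)
      }
    }
    idx$B[[s]] <- as_rle_array(codes)

    go <- which(codes > 0L)
    for (ns in unique(nxt[go])) {
      sel <- go[nxt[go] == ns]
      key <- paste0(opposite(s), "|", ns)
      queues[[key]] <- list(o = recs_o[sel], p = recs_p[sel] + 1L)
    }
  }
  idx
}
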