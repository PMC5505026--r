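#' @keywords internal
"_PACKAGE"

# ---- Side arithmetic --------------------------------------------------------
#
# A node k >= 1 has two sides: the left (5') side 2k - 1 and the right (3')
# side 2k. Side 0 is the distinguished null side: it belongs to no node and
# compares less than every real side. Sides are totally ordered by integer
# order; that order drives every adjacency listing and hence the c() function.

#' Side of a node
#'
#' Convert between node identifiers and side identifiers. Node `k` has left
#' side `2k - 1` and right side `2k`; `node_of()` inverts the numbering and
#' `opposite()` returns the other side of the same node.
#'
#' @param node positive integer node identifier(s).
#' @param s positive integer side identifier(s); the null side 0 is rejected.
#' @return An integer vector of sides (or node ids for `node_of()`).
#' @examples
#' left_side(3)    # 5
#' right_side(3)   # 6
#' opposite(5)     # 6
#' node_of(9)      # 5
#' @export
left_side <- function(node) {
  node <- as.integer(node)
  stopifnot(all(node >= 1L))
  2L * node - 1L
}

#' @rdname left_side
#' @export
right_side <- function(node) {
  node <- as.integer(node)
  stopifnot(all(node >= 1L))
  2L * node
}

#' @rdname left_side
#' @export
is_left_side <- function(s) {
  s <- as.integer(s)
  if (any(s < 1L)) stop("the null side (0) belongs to no node", call. = FALSE)
  s %% 2L == 1L
}

#' @rdname left_side
#' @export
opposite <- function(s) {
  s <- as.integer(s)
  if (any(s < 1L)) stop("the null side (0) has no opposite", call. = FALSE)
  s + ifelse(s %% 2L == 1L, 1L, -1L)
}

#' @rdname left_side
#' @export
node_of <- function(s) {
  s <- as.integer(s)
  if (any(s < 1L)) stop("the null side (0) belongs to no node", call. = FALSE)
  (s + 1L) %/% 2L
}

# ---- Bidirected genome graph ------------------------------------------------

#' Construct a bidirected genome graph
#'
#' A genome graph is a set of nodes carrying DNA-sequence labels together with
#' edges joining node *sides* (ends), so that sequence can be traversed in
#' either orientation. Edges are unordered pairs of sides; a self-loop
#' `{s, s}` is permitted, and at most one edge may join a given pair of sides.
#'
#' @param labels character vector of node labels over `A`,`C`,`G`,`T`,`N`
#'   (case-insensitive, stored upper-case). Names, if present, are node
#'   identifiers; otherwise nodes are numbered `1..length(labels)`.
#' @param edges two-column matrix (or data frame) of side identifiers, one row
#'   per edge, or `NULL` for an edgeless graph.
#' @return An object of class `bidirected_graph`.
#' @examples
#' g <- bidirected_graph(c("GAT", "T", "C", "ACA"),
#'                       rbind(c(2, 3), c(2, 5), c(6, 7), c(4, 7)))
#' adjacent_sides(g, 7)
#' @export
bidirected_graph <- function(labels, edges = NULL) {
  labels <- toupper(as.character(labels))
  if (is.null(names(labels))) {
    ids <- seq_along(labels)
  } else {
    ids <- as.integer(names(labels))
    if (anyNA(ids) || any(ids < 1L)) {
      stop("node identifiers must be positive integers", call. = FALSE)
    }
    if (anyDuplicated(ids)) stop("duplicate node identifiers", call. = FALSE)
  }
  if (length(labels) && any(!nzchar(labels))) {
    stop("node labels must be nonempty", call. = FALSE)
  }
  if (length(labels) && any(grepl("[^ACGTN]", labels))) {
    stop("node labels must be DNA over {A,C,G,T,N}", call. = FALSE)
  }
  max_id <- if (length(ids)) max(ids) else 0L
  lab <- rep(NA_character_, max_id)
  lab[ids] <- labels

  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(integer(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    storage.mode(em) <- "integer"
    if (ncol(em) != 2L) stop("edges must have two columns of sides", call. = FALSE)
    if (any(em < 1L)) stop("edge endpoints must be real sides (>= 1)", call. = FALSE)
    bad <- node_of(as.vector(em)) > max_id | is.na(lab[node_of(as.vector(em))])
    if (any(bad)) {
      stop("edge endpoint side ", as.vector(em)[which(bad)[1L]],
           " does not belong to any node", call. = FALSE)
    }
    em <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
    if (anyDuplicated(em)) {
      d <- em[duplicated(em), , drop = FALSE]
      stop("duplicate edge {", d[1L, 1L], ", ", d[1L, 2L], "}: only one edge ",
           "may connect a given pair of sides", call. = FALSE)
    }
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }

  n_sides <- 2L * max_id
  adj <- vector("list", n_sides)
  if (nrow(em)) {
    for (r in seq_len(nrow(em))) {
      a <- em[r, 1L]; b <- em[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      if (b != a) adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, function(x) if (is.null(x)) integer(0) else sort(x))
  } else {
    adj <- lapply(adj, function(x) integer(0))
  }

  structure(
    list(labels = lab, node_ids = sort(ids), edges = em, adj = adj,
         n_sides = n_sides),
    class = "bidirected_graph"
  )
}

#' @export
print.bidirected_graph <- function(x, ...) {
  cat("bidirected_graph: ", length(x$node_ids), " nodes (",
      sum(nchar(x$labels), na.rm = TRUE), " bp), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Sides adjacent to a side
#'
#' Returns the sides `x` with an edge `{x, s}` in the graph, in ascending side
#' order. This ordering is load-bearing: the c() function of a gPBWT index is
#' defined by prefix sums over it.
#'
#' @param g a [bidirected_graph()].
#' @param s a real side identifier.
#' @return Sorted integer vector of adjacent sides (a self-loop contributes
#'   `s` itself once).
#' @export
adjacent_sides <- function(g, s) {
  s <- as.integer(s)
  if (s < 1L || s > g$n_sides) stop("side ", s, " is not in the graph", call. = FALSE)
  g$adj[[s]]
}

#' Node label
#'
#' @param g a [bidirected_graph()].
#' @param node node identifier.
#' @return The node's DNA label.
#' @export
node_label <- function(g, node) {
  node <- as.integer(node)
  if (node < 1L || node > length(g$labels) || is.na(g$labels[node])) {
    stop("node ", node, " is not in the graph", call. = FALSE)
  }
  g$labels[node]
}

has_node <- function(g, node) {
  node >= 1L & node <= length(g$labels) & !is.na(g$labels[node])
}

has_edge <- function(g, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (a < 1L || b < 1L || a > g$n_sides || b > g$n_sides) return(FALSE)
  b %in% g$adj[[a]]
}

# ---- Construction from reference + variants ---------------------------------

#' Build a genome graph from a reference and nonoverlapping variants
#'
#' Starts from a single node holding the whole reference, then for each
#' variant breaks the reference chain so that the reference allele occupies a
#' single node, adds a node for the alternate allele, and attaches the
#' alternate node's left and right sides to everything attached to the
#' reference-allele node's left and right sides respectively. Variants are
#' replacements of a nonempty reference substring by a nonempty alternate
#' string and must not partially overlap (several alternates over the same
#' reference interval are allowed, as produced by splitting multiallelic
#' records).
#'
#' Node identifiers are assigned in reference order, each alternate node
#' directly after its reference-allele node, so output is deterministic.
#' Adjacent variants whose reference segments abut produce no empty nodes;
#' flanking nodes are connected directly.
#'
#' @param reference single DNA string.
#' @param variants data frame with columns `ref_start` (0-based offset),
#'   `ref` (reference allele) and `alt` (alternate allele), or `NULL`.
#' @return An object of class `graph_build`: a list with elements
#'   \describe{
#'     \item{graph}{the [bidirected_graph()]}
#'     \item{alleles}{tibble mapping each variant to its `ref_node` and
#'       `alt_node`}
#'     \item{backbone}{tibble of reference segments in order (`node`,
#'       `start`, `end`, half-open 0-based)}
#'   }
#' @examples
#' b <- graph_from_variants("GATTACA",
#'                          data.frame(ref_start = 3, ref = "T", alt = "C"))
#' b$graph   # 4 nodes: GAT, T, C, ACA
#' @export
graph_from_variants <- function(reference, variants = NULL) {
  reference <- toupper(as.character(reference))
  stopifnot(length(reference) == 1L, nchar(reference) >= 1L)
  if (grepl("[^ACGTN]", reference)) {
    stop("reference must be DNA over {A,C,G,T,N}", call. = FALSE)
  }
  n <- nchar(reference)

  if (is.null(variants) || NROW(variants) == 0L) {
    v <- data.frame(ref_start = integer(0), ref = character(0),
                    alt = character(0))
  } else {
    v <- as.data.frame(variants)[, c("ref_start", "ref", "alt")]
    v$ref_start <- as.integer(v$ref_start)
    v$ref <- toupper(as.character(v$ref))
    v$alt <- toupper(as.character(v$alt))
    if (any(!nzchar(v$ref)) || any(!nzchar(v$alt))) {
      stop("variant alleles must be nonempty strings", call. = FALSE)
    }
    if (any(v$ref_start < 0L) || any(v$ref_start + nchar(v$ref) > n)) {
      stop("variant lies outside the reference", call. = FALSE)
    }
  }
  v$end <- v$ref_start + nchar(v$ref)
  v$input_order <- seq_len(nrow(v))
  v <- v[order(v$ref_start, v$end, v$input_order), , drop = FALSE]

  # distinct intervals must be strictly nonoverlapping; identical intervals
  # (multiple alternates at one site) are fine
  if (nrow(v) > 1L) {
    for (i in 2L:nrow(v)) {
      same <- v$ref_start[i] == v$ref_start[i - 1L] && v$end[i] == v$end[i - 1L]
      if (!same && v$ref_start[i] < v$end[i - 1L]) {
        stop("overlapping variants at reference offsets ",
             v$ref_start[i - 1L], " and ", v$ref_start[i], call. = FALSE)
      }
    }
  }
  for (i in seq_len(nrow(v))) {
    seen <- substr(reference, v$ref_start[i] + 1L, v$end[i])
    if (seen != v$ref[i]) {
      stop("reference allele mismatch at offset ", v$ref_start[i],
           ": expected '", v$ref[i], "', reference has '", seen, "'",
           call. = FALSE)
    }
  }

  cuts <- sort(unique(c(0L, v$ref_start, v$end, n)))
  seg_start <- cuts[-length(cuts)]
  seg_end <- cuts[-1L]

  # assign node ids: reference segments in order, alternates right after
  # their reference-allele segment
  labels <- character(0)
  backbone_node <- integer(length(seg_start))
  v$ref_node <- rep(NA_integer_, nrow(v))
  v$alt_node <- rep(NA_integer_, nrow(v))
  next_id <- 0L
  for (k in seq_along(seg_start)) {
    next_id <- next_id + 1L
    backbone_node[k] <- next_id
    labels[next_id] <- substr(reference, seg_start[k] + 1L, seg_end[k])
    hit <- which(v$ref_start == seg_start[k] & v$end == seg_end[k])
    for (j in hit) {
      v$ref_node[j] <- backbone_node[k]
      next_id <- next_id + 1L
      v$alt_node[j] <- next_id
      labels[next_id] <- v$alt[j]
    }
  }

  # chain edges along the reference, then attach alternates in variant order;
  # attachment copies whatever is currently incident on the reference-allele
  # node's sides, so alternates of adjacent variants become connected too
  adj <- vector("list", 2L * next_id)
  add_edge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    if (b != a) adj[[b]] <<- c(adj[[b]], a)
  }
  for (k in seq_along(backbone_node)[-1L]) {
    add_edge(right_side(backbone_node[k - 1L]), left_side(backbone_node[k]))
  }
  ord <- order(v$ref_start, v$input_order)
  for (j in ord) {
    r <- v$ref_node[j]; a <- v$alt_node[j]
    for (x in adj[[left_side(r)]]) add_edge(x, left_side(a))
    for (x in adj[[right_side(r)]]) add_edge(x, right_side(a))
  }
  pairs <- do.call(rbind, lapply(seq_along(adj), function(s) {
    xs <- adj[[s]]
    if (is.null(xs)) return(NULL)
    cbind(pmin(s, xs), pmax(s, xs))
  }))
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2L)
  pairs <- unique(pairs)

  g <- bidirected_graph(labels, pairs)
  v <- v[order(v$input_order), , drop = FALSE]
  structure(
    list(
      graph = g,
      alleles = tibble::tibble(
        variant = v$input_order, ref_start = v$ref_start,
        ref_allele = v$ref, alt_allele = v$alt,
        ref_node = v$ref_node, alt_node = v$alt_node
      ),
      backbone = tibble::tibble(node = backbone_node, start = seg_start,
                                end = seg_end)
    ),
    class = "graph_build"
  )
}

#' @export
print.graph_build <- function(x, ...) {
  cat("graph_build: ", length(x$graph$node_ids), " nodes, ",
      nrow(x$graph$edges), " edges, ", nrow(x$alleles), " variants\n", sep = "")
  invisible(x)
}

# ---- DAG orientation --------------------------------------------------------

#' Check whether a graph admits a left-to-right DAG orientation
#'
#' Succeeds iff every edge joins the right side of one node to the left side
#' of a *different* node and the induced directed graph (right side to left
#' side) is acyclic. On success the returned topological order of nodes
#' induces the full ordering of sides that batch index construction requires.
#' Failure is returned as a value, not thrown, and names one offending edge
#' or the nodes of a cycle.
#'
#' @param g a [bidirected_graph()].
#' @return A list with `success` (logical) and either `order` (integer vector
#'   of node ids in topological order) or `reason` plus `edge`/`cycle`.
#' @examples
#' b <- graph_from_variants("GATTACA",
#'                          data.frame(ref_start = 3, ref = "T", alt = "C"))
#' dag_orientation(b$graph)$order
#' @export
dag_orientation <- function(g) {
  fail <- function(reason, edge = NULL, cycle = NULL) {
    list(success = FALSE, reason = reason, edge = edge, cycle = cycle)
  }
  em <- g$edges
  for (r in seq_len(nrow(em))) {
    a <- em[r, 1L]; b <- em[r, 2L]
    if (a == b) {
      return(fail(sprintf("self-loop edge {%d, %d}", a, b), edge = c(a, b)))
    }
    odd_a <- a %% 2L == 1L; odd_b <- b %% 2L == 1L
    if (odd_a == odd_b || node_of(a) == node_of(b)) {
      return(fail(sprintf(
        "edge {%d, %d} does not join the right side of one node to the left side of another",
        a, b), edge = c(a, b)))
    }
  }
  ids <- g$node_ids
  if (!length(ids)) return(list(success = TRUE, order = integer(0)))

  # Kahn's algorithm, always taking the smallest ready node id so the order
  # is deterministic
  from <- node_of(ifelse(em[, 1L] %% 2L == 0L, em[, 1L], em[, 2L]))
  to <- node_of(ifelse(em[, 1L] %% 2L == 1L, em[, 1L], em[, 2L]))
  indeg <- stats::setNames(integer(length(ids)), ids)
  out <- split(to, from)
  for (t in to) indeg[as.character(t)] <- indeg[as.character(t)] + 1L
  order_out <- integer(0)
  ready <- sort(ids[indeg[as.character(ids)] == 0L])
  while (length(ready)) {
    nd <- ready[1L]; ready <- ready[-1L]
    order_out <- c(order_out, nd)
    for (t in out[[as.character(nd)]]) {
      key <- as.character(t)
      indeg[key] <- indeg[key] - 1L
      if (indeg[key] == 0L) ready <- sort(c(ready, t))
    }
  }
  if (length(order_out) < length(ids)) {
    return(fail("cycle among nodes",
                cycle = sort(setdiff(ids, order_out))))
  }
  list(success = TRUE, order = order_out)
}
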