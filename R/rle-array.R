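# Run-length-compressed integer array with rank-before and positional insert.
#
# This is the storage contract the gPBWT's B[] arrays need and nothing more:
# no wavelet tree, no select. Values are small non-negative integers (local
# edge codes). Runs are kept maximal at all times, so two arrays with equal
# logical content are identical() and serialize bit-exactly.

#' Run-length-compressed integer array
#'
#' Stores a logical sequence of small non-negative integers as maximal runs
#' of `(value, length)` pairs, supporting positional access, rank-before
#' queries and positional insertion. All positions are 0-based, matching the
#' index arithmetic of the surrounding transform.
#'
#' @param values integer vector of run values (adjacent runs must differ).
#' @param lengths positive integer vector of run lengths.
#' @param x integer vector to compress (`as_rle_array`).
#' @param a an `rle_array`.
#' @param i 0-based position.
#' @param v non-negative integer value.
#' @return `rle_array()` and `as_rle_array()` return an `rle_array`;
#'   `rla_value_at()` the value at position `i`; `rla_rank_before()` the
#'   number of positions `j < i` holding `v`; `rla_insert_at()` the updated
#'   array; `rla_run_count()` the number of maximal runs.
#' @examples
#' a <- as_rle_array(c(9L, 7L, 7L))
#' rla_value_at(a, 1)        # 7
#' rla_rank_before(a, 7, 3)  # 2
#' rla_run_count(rla_insert_at(a, 1, 7))  # still 2 runs
#' @export
rle_array <- function(values = integer(0), lengths = integer(0)) {
  values <- as.integer(values)
  lengths <- as.integer(lengths)
  if (length(values) != length(lengths)) {
    stop("values and lengths must have equal length", call. = FALSE)
  }
  if (any(lengths < 1L)) stop("run lengths must be positive", call. = FALSE)
  if (any(values < 0L)) stop("run values must be non-negative", call. = FALSE)
  if (length(values) > 1L && any(values[-1L] == values[-length(values)])) {
    stop("adjacent runs must have distinct values (runs must be maximal)",
         call. = FALSE)
  }
  structure(list(values = values, lengths = lengths,
                 n = sum(lengths)),
            class = "rle_array")
}

#' @rdname rle_array
#' @export
as_rle_array <- function(x) {
  x <- as.integer(x)
  if (!length(x)) return(rle_array())
  r <- rle(x)
  rle_array(r$values, r$lengths)
}

#' @export
as.integer.rle_array <- function(x, ...) rep(x$values, x$lengths)

#' @export
length.rle_array <- function(x) x$n

#' @export
print.rle_array <- function(x, ...) {
  cat("rle_array: length ", x$n, ", ", length(x$values), " runs\n", sep = "")
  invisible(x)
}

#' @rdname rle_array
#' @export
rla_run_count <- function(a) length(a$values)

#' @rdname rle_array
#' @export
rla_value_at <- function(a, i) {
  i <- as.integer(i)
  if (i < 0L || i >= a$n) {
    stop("position ", i, " out of range [0, ", a$n, ")", call. = FALSE)
  }
  r <- findInterval(i, cumsum(a$lengths)) + 1L
  a$values[r]
}

#' @rdname rle_array
#' @export
rla_rank_before <- function(a, v, i) {
  i <- as.integer(i); v <- as.integer(v)
  if (i < 0L || i > a$n) {
    stop("position ", i, " out of range [0, ", a$n, "]", call. = FALSE)
  }
  if (i == 0L || !length(a$values)) return(0L)
  starts <- cumsum(c(0L, a$lengths))[seq_along(a$lengths)]
  overlap <- pmin(pmax(i - starts, 0L), a$lengths)
  sum(overlap[a$values == v])
}

#' @rdname rle_array
#' @export
rla_insert_at <- function(a, i, v) {
  i <- as.integer(i); v <- as.integer(v)
  if (v < 0L) stop("run values must be non-negative", call. = FALSE)
  if (i < 0L || i > a$n) {
    stop("position ", i, " out of range [0, ", a$n, "]", call. = FALSE)
  }
  vals <- a$values; lens <- a$lengths
  nr <- length(vals)
  if (nr == 0L) {
    return(structure(list(values = v, lengths = 1L, n = 1L),
                     class = "rle_array"))
  }
  ends <- cumsum(lens)
  starts <- ends - lens
  # run whose interior contains i (starts[r] < i < ends[r]), if any
  r <- findInterval(i, ends) + 1L   # first run with ends[r] > i, or nr+1 at i==n
  if (r <= nr && i > starts[r]) {
    # interior of run r
    if (vals[r] == v) {
      lens[r] <- lens[r] + 1L
    } else {
      pre <- i - starts[r]
      vals <- c(vals[seq_len(r - 1L)], vals[r], v, vals[r:nr])
      lens <- c(lens[seq_len(r - 1L)], pre, 1L, lens[r] - pre,
                if (r < nr) lens[(r + 1L):nr])
    }
  } else {
    # boundary before run r (r == nr + 1 means append at the end)
    left <- r - 1L
    if (left >= 1L && vals[left] == v) {
      lens[left] <- lens[left] + 1L
    } else if (r <= nr && vals[r] == v) {
      lens[r] <- lens[r] + 1L
    } else {
      vals <- append(vals, v, after = left)
      lens <- append(lens, 1L, after = left)
    }
  }
  structure(list(values = vals, lengths = lens, n = a$n + 1L),
            class = "rle_array")
}

# binary writer/reader used inside the index envelope: run count, then the
# (value, length) pairs, all little-endian int32
rla_write <- function(a, con) {
  writeBin(length(a$values), con, size = 4L, endian = "little")
  if (length(a$values)) {
    writeBin(as.integer(rbind(a$values, a$lengths)), con, size = 4L,
             endian = "little")
  }
  invisible(NULL)
}

rla_read <- function(con) {
  nr <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(nr) != 1L || is.na(nr) || nr < 0L) {
    stop("malformed run-length array serialization", call. = FALSE)
  }
  if (nr == 0L) return(rle_array())
  flat <- readBin(con, "integer", n = 2L * nr, size = 4L, endian = "little")
  if (length(flat) != 2L * nr) {
    stop("truncated run-length array serialization", call. = FALSE)
  }
  m <- matrix(flat, nrow = 2L)
  rle_array(m[1L, ], m[2L, ])
}
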