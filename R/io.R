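# Format I/O: FASTA references, GFA 1.0 graphs and paths, VCF variants, and
# phased-haplotype import with splitting of invalid pieces.
#
# GFA mapping: S lines are nodes; an L line records edge {s, s'} as a link
# leaving n(s) (orientation "+" iff s is a right side) and entering n(s')
# (orientation "+" iff s' is a left side), overlap "0M". P lines are node
# paths, i.e. thread orientations. Containment (C) lines are rejected.
# Internal coordinates are 0-based half-open; VCF POS is converted on read.

#' Read a reference sequence from FASTA
#'
#' @param path FASTA file.
#' @param name optional record name; by default the first record is used.
#' @return A single upper-case DNA string.
#' @export
read_reference_fasta <- function(path, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no sequences in ", path, call. = FALSE)
  if (is.null(name)) {
    s <- seqs[[1L]]
  } else {
    hit <- which(sub("\\s.*$", "", names(seqs)) == name)
    if (!length(hit)) stop("no FASTA record named '", name, "'", call. = FALSE)
    s <- seqs[[hit[1L]]]
  }
  toupper(as.character(s))
}

# ---- GFA --------------------------------------------------------------------

#' Write a graph (and optionally thread paths) as GFA 1.0
#'
#' @param g a [bidirected_graph()].
#' @param path output file.
#' @param paths optional named list of thread orientations, written as P
#'   lines.
#' @return The path, invisibly.
#' @export
write_gfa <- function(g, path, paths = NULL) {
  lines <- "H\tVN:Z:1.0"
  for (id in g$node_ids) {
    lines <- c(lines, paste("S", id, g$labels[id], sep = "\t"))
  }
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      a <- g$edges[r, 1L]; b <- g$edges[r, 2L]
      lines <- c(lines, paste(
        "L", node_of(a), if (a %% 2L == 0L) "+" else "-",
        node_of(b), if (b %% 2L == 1L) "+" else "-", "0M", sep = "\t"))
    }
  }
  if (!is.null(paths)) {
    nms <- names(paths)
    if (is.null(nms)) nms <- paste0("thread_", seq_along(paths))
    for (k in seq_along(paths)) {
      np <- thread_to_node_path(paths[[k]])
      lines <- c(lines, paste(
        "P", nms[k],
        paste0(np$nodes, ifelse(np$forward, "+", "-"), collapse = ","),
        "*", sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFA 1.0 graph and its paths
#'
#' @param path GFA file. Node names must be integers; containment (C) lines
#'   are rejected; link overlaps must be `0M` or `*`.
#' @return A list with `graph` (a [bidirected_graph()]) and `paths` (named
#'   list of thread orientations from P lines).
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) {
    stop("GFA file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rtype <- substr(lines, 1L, 1L)
  if (any(rtype == "C")) {
    stop("GFA containment (C) lines are not supported", call. = FALSE)
  }
  split_fields <- function(x) strsplit(x, "\t", fixed = TRUE)

  s_fields <- split_fields(lines[rtype == "S"])
  if (!length(s_fields)) stop("GFA contains no S lines", call. = FALSE)
  ids <- vapply(s_fields, function(f) f[2L], character(1))
  if (anyNA(suppressWarnings(as.integer(ids)))) {
    stop("GFA node names must be integers", call. = FALSE)
  }
  labels <- vapply(s_fields, function(f) f[3L], character(1))
  names(labels) <- ids

  em <- NULL
  l_fields <- split_fields(lines[rtype == "L"])
  if (length(l_fields)) {
    em <- t(vapply(l_fields, function(f) {
      if (length(f) >= 6L && !(f[6L] %in% c("0M", "*"))) {
        stop("GFA link overlaps other than 0M are not supported",
             call. = FALSE)
      }
      na <- as.integer(f[2L]); nb <- as.integer(f[4L])
      s <- if (f[3L] == "+") right_side(na) else left_side(na)
      sp <- if (f[5L] == "+") left_side(nb) else right_side(nb)
      c(s, sp)
    }, integer(2)))
    em <- unique(cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L])))
  }
  g <- bidirected_graph(labels, em)

  paths <- list()
  p_fields <- split_fields(lines[rtype == "P"])
  for (f in p_fields) {
    steps <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
    nodes <- as.integer(sub("[+-]$", "", steps))
    fwd <- grepl("\\+$", steps)
    paths[[f[2L]]] <- thread_from_node_path(g, nodes, fwd)
  }
  list(graph = g, paths = paths)
}

# ---- VCF --------------------------------------------------------------------

#' Read variants from a VCF
#'
#' Multiallelic records are split into one row per alternate allele;
#' symbolic or breakend alternates are rejected. Positions are converted to
#' 0-based offsets.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return A tibble with columns `ref_start` (0-based), `ref`, `alt`,
#'   `record` (originating VCF record number) and `allele_index` (1-based
#'   alternate index within the record).
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  out <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1L]]
    if (any(grepl("[][<>]", alts)) || any(alts == "*")) {
      stop("symbolic or breakend ALT alleles are not supported (record ", r,
           ")", call. = FALSE)
    }
    out[[r]] <- tibble::tibble(
      ref_start = as.integer(fix[r, "POS"]) - 1L,
      ref = toupper(fix[r, "REF"]),
      alt = toupper(alts),
      record = r,
      allele_index = seq_along(alts)
    )
  }
  do.call(rbind, out)
}

# ---- Phased haplotype import ------------------------------------------------

#' Import phased haplotypes from a VCF as threads
#'
#' Walks, per sample and per haplotype, the reference node chain of a
#' [graph_from_variants()] build, substituting alternate-allele nodes where
#' the phased genotype selects them. Wherever the haplotype cannot be
#' continued as a single valid walk the current piece is emitted and a new
#' one started (a *split*):
#' \describe{
#'   \item{unphased}{a heterozygous genotype with the `/` separator -- the
#'     allele's phase is unknown, so the variant site is skipped}
#'   \item{missing}{a missing call (`.`); site skipped}
#'   \item{haploid}{a haploid call in diploid import; site skipped}
#'   \item{no_edge}{consecutive chosen allele nodes not joined by an edge;
#'     the new piece begins at the offending node}
#' }
#' Homozygous unphased genotypes (`0/0`, `1/1`) are unambiguous and do not
#' split. A variant present in the VCF but absent from the build's allele
#' map is an error.
#'
#' @param path VCF with phased sample genotypes.
#' @param build a `graph_build` from [graph_from_variants()] constructed
#'   from the same variants.
#' @param ploidy haplotypes per sample (default 2).
#' @return A list with `threads` (named list of thread orientations) and
#'   `report` (a `haplotype_import_report`: sample/haplotype/thread counts,
#'   split count and per-reason split tallies).
#' @export
import_phased_vcf <- function(path, build, ploidy = 2L) {
  stopifnot(inherits(build, "graph_build"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    stop("VCF has no sample genotype columns", call. = FALSE)
  }
  samples <- colnames(gt_raw)[-1L]
  gt <- sub(":.*$", "", gt_raw[, -1L, drop = FALSE])

  # map record r, alternate allele index j -> alleles row of the build
  al <- build$alleles
  rec_site <- integer(nrow(fix))      # backbone ref node per record
  rec_alt <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    pos0 <- as.integer(fix[r, "POS"]) - 1L
    ref <- toupper(fix[r, "REF"])
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1L]]
    rows <- vapply(toupper(alts), function(a) {
      hit <- which(al$ref_start == pos0 & al$ref_allele == ref &
                   al$alt_allele == a)
      if (!length(hit)) {
        stop("VCF variant at POS ", pos0 + 1L, " (", ref, ">", a,
             ") has no mapped allele node in the graph", call. = FALSE)
      }
      hit[1L]
    }, integer(1))
    rec_alt[[r]] <- rows
    rec_site[r] <- al$ref_node[rows[1L]]
  }
  site_record <- stats::setNames(seq_len(nrow(fix)), rec_site)

  g <- build$graph
  threads <- list()
  n_splits <- 0L
  reasons <- c(unphased = 0L, missing = 0L, haploid = 0L, no_edge = 0L,
               other = 0L)

  for (smp in seq_along(samples)) {
    for (hap in seq_len(ploidy)) {
      piece <- integer(0)
      flush <- function() {
        if (length(piece)) {
          nm <- paste0(samples[smp], "_hap", hap, "_",
                       length(threads) + 1L)
          threads[[nm]] <<- thread_from_node_path(
            g, piece, rep(TRUE, length(piece)))
        }
        piece <<- integer(0)
      }
      break_at <- function(reason) {
        if (length(piece)) {
          n_splits <<- n_splits + 1L
          reasons[reason] <<- reasons[reason] + 1L
        }
        flush()
      }
      for (k in seq_len(nrow(build$backbone))) {
        node <- build$backbone$node[k]
        rec <- site_record[as.character(node)]
        if (!is.na(rec)) {
          gt_str <- gt[rec, smp]
          if (is.na(gt_str) || !nzchar(gt_str)) {
            break_at("missing"); next
          }
          fields <- strsplit(gt_str, "[|/]")[[1L]]
          phased <- !grepl("/", gt_str, fixed = TRUE)
          if (all(fields %in% c(".", ""))) {
            break_at("missing"); next
          }
          if (length(fields) < ploidy) {
            break_at("haploid"); next
          }
          a_chr <- fields[hap]
          if (a_chr %in% c(".", "")) {
            break_at("missing"); next
          }
          het <- length(unique(fields[fields != "."])) > 1L
          if (!phased && het) {
            break_at("unphased"); next
          }
          a <- suppressWarnings(as.integer(a_chr))
          if (is.na(a) || a > length(rec_alt[[rec]])) {
            stop("genotype allele '", a_chr, "' at record ", rec,
                 " has no mapped allele node", call. = FALSE)
          }
          node <- if (a == 0L) node else al$alt_node[rec_alt[[rec]][a]]
        }
        if (length(piece) &&
            !has_edge(g, right_side(piece[length(piece)]), left_side(node))) {
          break_at("no_edge")
        }
        piece <- c(piece, node)
      }
      flush()
    }
  }

  report <- structure(
    list(n_samples = length(samples),
         n_haplotypes = length(samples) * ploidy,
         n_threads_emitted = length(threads),
         n_splits = n_splits,
         split_reasons = reasons),
    class = "haplotype_import_report"
  )
  list(threads = threads, report = report)
}

#' @export
print.haplotype_import_report <- function(x, ...) {
  cat("haplotype import: ", x$n_haplotypes, " haplotypes from ",
      x$n_samples, " samples -> ", x$n_threads_emitted, " threads (",
      x$n_splits, " splits",
      if (x$n_splits)
        paste0("; ", paste(names(x$split_reasons)[x$split_reasons > 0L],
                           x$split_reasons[x$split_reasons > 0L],
                           sep = "=", collapse = ", ")),
      ")\n", sep = "")
  invisible(x)
}
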