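#' Genomic interval tables
#'
#' Throughout the package a set of genomic intervals (a peak set, a reference
#' enhancer set, a tile set) is an ordinary tibble with columns `chrom`
#' (character), `start` and `end` (0-based half-open integers, `start < end`),
#' and optionally `id` (unique character), `score` (numeric) and `strand`
#' (`"+"`, `"-"` or `"."`). `genomic_intervals()` validates and canonicalises
#' such a table: missing ids are filled with `"chrom:start-end"`, rows are
#' sorted by `(chrom, start, end, id)` and the invariants are enforced.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param fixed_width Optional integer; if supplied, every interval must have
#'   exactly this width.
#' @return A tibble with columns `chrom`, `start`, `end`, `id`, `score`,
#'   `strand`, sorted and with unique ids.
#' @examples
#' genomic_intervals(data.frame(chrom = "chr1", start = 0, end = 500))
#' @export
genomic_intervals <- function(x, fixed_width = NULL) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(x)
  out$chrom <- as.character(out$chrom)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (any(is.na(out$chrom)) || any(!nzchar(out$chrom))) stop("chrom must be non-empty")
  if (any(is.na(out$start)) || any(is.na(out$end))) stop("start/end must be integers")
  if (any(out$start < 0)) stop("start must be >= 0")
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    stop("start >= end for interval(s) at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(fixed_width) && any(out$end - out$start != fixed_width)) {
    stop("intervals are not all of fixed width ", fixed_width)
  }
  if (!"id" %in% names(out) || all(is.na(out$id))) {
    out$id <- paste0(out$chrom, ":", out$start, "-", out$end)
  } else {
    out$id <- as.character(out$id)
    fill <- is.na(out$id) | !nzchar(out$id)
    out$id[fill] <- paste0(out$chrom, ":", out$start, "-", out$end)[fill]
  }
  if (anyDuplicated(out$id)) {
    stop("interval ids are not unique: e.g. ", out$id[duplicated(out$id)][1])
  }
  if (!"score" %in% names(out)) out$score <- NA_real_
  out$score <- as.numeric(out$score)
  if (!"strand" %in% names(out)) out$strand <- "."
  out$strand <- as.character(out$strand)
  if (!all(out$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  out <- out[order(out$chrom, out$start, out$end, out$id), , drop = FALSE]
  out[, c("chrom", "start", "end", "id", "score", "strand")]
}

#' @keywords internal
#' @noRd
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    id = x$id
  )
}

#' Read and write BED files
#'
#' BED is tab-separated and already 0-based half-open, so coordinates are
#' preserved verbatim. Columns beyond the third are mapped to `id` (4th),
#' `score` (5th) and `strand` (6th) when present. Parsing is strict: a line
#' with fewer than three fields, a non-numeric coordinate or `start >= end`
#' raises an error naming the offending line.
#'
#' @param path Path to a BED3/BED6 file.
#' @return A sorted interval tibble (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(genomic_intervals(tibble::tibble(
      chrom = character(), start = integer(), end = integer()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 tab-separated fields")
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(starts) || anyNA(ends)) {
    stop("malformed BED line ", which(is.na(starts) | is.na(ends))[1], ": non-integer coordinate")
  }
  bad <- which(starts >= ends)
  if (length(bad) > 0) stop("start >= end at BED line ", bad[1])
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = starts,
    end = ends
  )
  if (all(nf >= 4)) out$id <- vapply(fields, `[[`, "", 4)
  if (all(nf >= 5)) out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
  if (all(nf >= 6)) out$strand <- vapply(fields, `[[`, "", 6)
  genomic_intervals(out)
}

#' @param intervals An interval tibble.
#' @param path Output path.
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  intervals <- genomic_intervals(intervals)
  df <- data.frame(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    id = intervals$id,
    score = ifelse(is.na(intervals$score), 0, intervals$score),
    strand = intervals$strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert between printed genome-browser coordinates and intervals
#'
#' Printed coordinates such as `"chr15:60,223,133-60,223,633"` follow the
#' genome-browser convention: 1-based with an inclusive end. On ingest they
#' are converted to the package's 0-based half-open convention, `[a-1, b)`,
#' so the printed range `a..b` has width `b - a + 1`. With
#' `one_based = FALSE` the text is taken verbatim as 0-based half-open.
#'
#' @param text A string `"chrN:a-b"`; digit grouping commas are allowed.
#' @param one_based Is the printed text 1-based inclusive (default `TRUE`)?
#' @return A one-row interval tibble.
#' @examples
#' from_printed_coordinates("chr1:1-1")          # the smallest legal interval
#' from_printed_coordinates("chrX:23,434,983-23,435,483")
#' @export
from_printed_coordinates <- function(text, one_based = TRUE) {
  stopifnot(is.character(text), length(text) == 1)
  clean <- gsub(",", "", text, fixed = TRUE)
  m <- regmatches(clean, regexec("^([^:]+):([0-9]+)-([0-9]+)$", clean))[[1]]
  if (length(m) != 4) stop("cannot parse coordinates: ", text)
  a <- as.integer(m[3])
  b <- as.integer(m[4])
  if (b < a) stop("end before start in: ", text)
  if (one_based) {
    if (a < 1) stop("1-based coordinate must be >= 1: ", text)
    start <- a - 1L
    end <- b
  } else {
    start <- a
    end <- b
    if (start >= end) stop("zero-width 0-based interval: ", text)
  }
  genomic_intervals(tibble::tibble(chrom = m[2], start = start, end = end))
}

#' @param interval A one-row interval tibble.
#' @rdname from_printed_coordinates
#' @export
to_printed_coordinates <- function(interval, one_based = TRUE) {
  stopifnot(nrow(interval) == 1)
  if (one_based) {
    paste0(interval$chrom, ":", interval$start + 1L, "-", interval$end)
  } else {
    paste0(interval$chrom, ":", interval$start, "-", interval$end)
  }
}

#' Overlapping pairs between two interval sets
#'
#' Reports every pair of intervals whose intersection is at least
#' `min_overlap` base pairs, the same containment rule the cancer-specific
#' enhancer subtraction uses (half-open intervals sharing only a boundary do
#' not overlap).
#'
#' @param a,b Interval tibbles.
#' @param min_overlap Minimum intersection length in bp (default 1).
#' @return A tibble with columns `id_a`, `id_b`, `overlap_bp`.
#' @export
find_overlaps <- function(a, b, min_overlap = 1L) {
  stopifnot(min_overlap >= 1)
  a <- genomic_intervals(a)
  b <- genomic_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(id_a = character(), id_b = character(), overlap_bp = integer()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      minoverlap = as.integer(min_overlap))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  out <- tibble::tibble(id_a = a$id[qi], id_b = b$id[si], overlap_bp = as.integer(ov))
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Gene model tables
#'
#' Gene models are tibbles with columns `gene_id`, `chrom`, `start`, `end`
#' (0-based half-open gene body), `strand` (`+`/`-`) and `tss` (the
#' strand-aware 5' end: `start` on `+`, `end - 1` on `-`). They are read and
#' written as 6-column TSV with a header.
#'
#' @param x A data frame with the six gene-model columns (`tss` optional on
#'   input; recomputed from the strand when absent).
#' @return A validated gene-model tibble sorted by `(chrom, start)`.
#' @export
gene_models <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  out <- tibble::as_tibble(x)
  out$gene_id <- as.character(out$gene_id)
  out$chrom <- as.character(out$chrom)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$strand <- as.character(out$strand)
  if (anyDuplicated(out$gene_id)) stop("gene_ids are not unique")
  if (!all(out$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (any(out$start >= out$end)) stop("gene body start >= end")
  tss <- ifelse(out$strand == "+", out$start, out$end - 1L)
  if ("tss" %in% names(out) && !all(is.na(out$tss))) {
    if (!all(as.integer(out$tss) == tss)) {
      stop("tss column inconsistent with strand-aware 5' end of the gene body")
    }
  }
  out$tss <- as.integer(tss)
  out <- out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
  out[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
}

#' @param path Path to a gene-model TSV.
#' @rdname gene_models
#' @export
read_gene_models <- function(path) {
  gene_models(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' @param genes A gene-model tibble.
#' @rdname gene_models
#' @export
write_gene_models <- function(genes, path) {
  readr::write_tsv(gene_models(genes), path, progress = FALSE)
  invisible(path)
}
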