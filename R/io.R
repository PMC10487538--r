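#' Read and write CellRanger-style sparse count matrices
#'
#' A counts directory holds `matrix.mtx` (MatrixMarket coordinate integer,
#' features x barcodes, as emitted by CellRanger), `barcodes.tsv` and
#' `features.tsv`. In memory the package orients counts as cells x features
#' (a `dgCMatrix` with barcodes as rownames and feature ids as colnames).
#' The round trip `write_counts_mtx()` then `read_counts_mtx()` is lossless.
#'
#' @param dir Directory containing the three files.
#' @return A sparse `dgCMatrix`, cells in rows, features in columns.
#' @export
read_counts_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) stop("missing file(s): ", paste(missing, collapse = ", "))
  m <- Matrix::readMM(paths[1])
  barcodes <- readLines(paths[2])
  features <- readLines(paths[3])
  # features.tsv may carry extra columns; the first is the id
  features <- vapply(strsplit(features, "\t", fixed = TRUE), `[[`, "", 1)
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d features x %d barcodes but features.tsv has %d and barcodes.tsv has %d entries",
      nrow(m), ncol(m), length(features), length(barcodes)
    ))
  }
  if (any(m@x < 0)) stop("negative entries in count matrix")
  if (any(m@x != round(m@x))) stop("non-integer entries in count matrix")
  out <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(out) <- list(barcodes, features)
  out
}

#' @param counts A cells x features matrix with dimnames.
#' @rdname read_counts_mtx
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(Matrix::t(counts), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read gene-set collections in GMT format
#'
#' @param path Path to a GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  fgsea::gmtPathways(path)
}

#' @param sets A named list of character vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read DNA sequences from FASTA
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' @param seqs A named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
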