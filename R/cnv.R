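#' Copy-number residual profiles inferred from expression
#'
#' Implements the reference-based expression-smoothing approach to CNV
#' inference: lowly expressed genes are dropped (`mean normalized counts <
#' expr_cutoff`), each gene's log expression is centered on the reference
#' mean, a truncated moving average over `window` genome-ordered genes is
#' applied per chromosome, each cell is re-centered by its median, and
#' residuals within `denoise_sd` reference standard deviations of zero are
#' shrunk to zero.
#'
#' @param normalized Cells x genes log-normalized expression.
#' @param genes A gene-model tibble covering (at least) the matrix genes;
#'   genes absent from it are ignored.
#' @param reference_cells Character vector of presumed-diploid cells (e.g.
#'   immune and endothelial clusters); must be non-empty.
#' @param expr_cutoff Mean de-logged expression cutoff (default 0.1).
#' @param window Moving-average window in genes, odd (default 101).
#' @param denoise_sd Denoising width in reference SDs (default 1.5).
#' @param exclude_chroms Chromosomes excluded from the genome ordering
#'   (default "chrM").
#' @return A `cnv_profile`: list with `residuals` (cells x genes, genome
#'   ordered), `genes` (the ordered gene models used), `reference_cells`,
#'   and `scores` (tibble: `cell`, `cnv_score` = mean squared residual).
#' @export
infer_cnv <- function(normalized, genes, reference_cells, expr_cutoff = 0.1,
                      window = 101, denoise_sd = 1.5,
                      exclude_chroms = "chrM") {
  if (window %% 2 == 0) stop("window must be odd")
  genes <- gene_models(genes)
  genes <- genes[!genes$chrom %in% exclude_chroms, , drop = FALSE]
  genes <- genes[genes$gene_id %in% colnames(normalized), , drop = FALSE]
  reference_cells <- intersect(reference_cells, rownames(normalized))
  if (length(reference_cells) == 0) stop("reference group is empty")
  x <- as.matrix(normalized[, genes$gene_id, drop = FALSE])
  mean_expr <- colMeans(expm1(x))
  keep <- mean_expr >= expr_cutoff
  genes <- genes[keep, , drop = FALSE]
  x <- x[, keep, drop = FALSE]
  ref_mean <- colMeans(x[reference_cells, , drop = FALSE])
  x <- sweep(x, 2, ref_mean, "-")
  # truncated moving average along the genome, per chromosome; positions
  # whose window had full support are flagged, because truncated edge
  # windows average fewer genes and carry systematically inflated variance
  h <- (window - 1) / 2
  interior <- rep(TRUE, ncol(x))
  for (chrom in unique(genes$chrom)) {
    idx <- which(genes$chrom == chrom)
    if (length(idx) < window) {
      warning("chromosome ", chrom, " has fewer genes (", length(idx),
              ") than the window; using truncated windows throughout")
    }
    x[, idx] <- t(truncated_moving_average(t(x[, idx, drop = FALSE]), window))
    pos <- seq_along(idx)
    interior[idx] <- pos > h & pos <= length(idx) - h
  }
  x <- sweep(x, 1, apply(x, 1, stats::median), "-")
  ref_sd <- stats::sd(as.vector(x[reference_cells, , drop = FALSE]))
  x[abs(x) < denoise_sd * ref_sd] <- 0
  score_cols <- if (any(interior)) which(interior) else seq_len(ncol(x))
  structure(
    list(
      residuals = x,
      genes = genes,
      interior = interior,
      reference_cells = reference_cells,
      scores = tibble::tibble(
        cell = rownames(x),
        cnv_score = rowMeans(x[, score_cols, drop = FALSE]^2)
      )
    ),
    class = "cnv_profile"
  )
}

# moving average over rows (genes) with truncated edge windows
truncated_moving_average <- function(mat, window) {
  n <- nrow(mat)
  h <- (window - 1) / 2
  cs <- apply(mat, 2, cumsum)
  cs <- rbind(0, cs)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' @noRd
#' @exportS3Method base::print
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> %d cells x %d genes (%d reference cells)\n",
              nrow(x$residuals), ncol(x$residuals), length(x$reference_cells)))
  invisible(x)
}

#' Three-way malignancy classification from a CNV profile
#'
#' The cells with the top `top_pct` CNV scores define a putative-tumor mean
#' profile; every cell then gets a correlation with that profile. Cells with
#' high score and high correlation are called tumor, cells low in both are
#' called normal, and the rest unassigned. When cluster assignments are
#' given, each cluster receives the majority call unless more than
#' `max_disagreement` of its cells disagree with the majority, in which case
#' the cluster is unassigned. Reference cells are never called tumor: they
#' anchor the score thresholds.
#'
#' @param profile A `cnv_profile` from [infer_cnv()].
#' @param top_pct Fraction of cells defining the putative-tumor profile
#'   (default 0.05).
#' @param score_hi_quantile Tumor requires a score above this quantile of the
#'   reference scores (default 0.7).
#' @param corr_min Tumor requires correlation above this value; normal
#'   requires at most this value (default 0.3).
#' @param score_lo_quantile Normal requires a score at or below this quantile
#'   of the reference scores (default 0.5).
#' @param clusters Optional tibble with `cell`, `cluster` for cluster-level
#'   calls.
#' @param max_disagreement Cluster unassigned above this disagreement
#'   fraction (default 0.3).
#' @return A list with `cells` (tibble: `cell`, `cnv_score`,
#'   `cnv_correlation`, `call`) and, when clusters are supplied, `clusters`
#'   (tibble: `cluster`, `call`, `agreement`).
#' @export
classify_malignant <- function(profile, top_pct = 0.05,
                               score_hi_quantile = 0.7, corr_min = 0.3,
                               score_lo_quantile = 0.5, clusters = NULL,
                               max_disagreement = 0.3) {
  stopifnot(inherits(profile, "cnv_profile"))
  res <- profile$residuals
  if (!is.null(profile$interior) && any(profile$interior)) {
    res <- res[, profile$interior, drop = FALSE]
  }
  n <- nrow(res)
  if (n < 20) stop("need at least 20 cells for a stable top-", top_pct, " profile")
  score <- profile$scores$cnv_score
  names(score) <- profile$scores$cell
  n_top <- max(1L, ceiling(top_pct * n))
  top_cells <- names(sort(score, decreasing = TRUE))[seq_len(n_top)]
  top_profile <- colMeans(res[top_cells, , drop = FALSE])
  sds <- apply(res, 1, stats::sd)
  corr <- rep(0, n)
  ok <- sds > 0 & stats::sd(top_profile) > 0
  corr[ok] <- as.numeric(stats::cor(t(res[ok, , drop = FALSE]), top_profile))
  ref_scores <- score[profile$reference_cells]
  score_hi <- stats::quantile(ref_scores, score_hi_quantile, names = FALSE)
  score_lo <- stats::quantile(ref_scores, score_lo_quantile, names = FALSE)
  call <- rep("unassigned", n)
  call[score > score_hi & corr > corr_min] <- "tumor"
  call[score <= score_lo & corr <= corr_min] <- "normal"
  is_ref <- rownames(res) %in% profile$reference_cells
  call[is_ref & call == "tumor"] <- "unassigned"
  cells <- tibble::tibble(
    cell = rownames(res),
    cnv_score = as.numeric(score),
    cnv_correlation = corr,
    call = call
  )
  out <- list(cells = cells)
  if (!is.null(clusters)) {
    out$clusters <- clusters |>
      dplyr::inner_join(cells, by = "cell") |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(
        majority = names(sort(table(.data$call), decreasing = TRUE))[1],
        agreement = max(table(.data$call)) / dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(call = ifelse(.data$agreement < 1 - max_disagreement,
                                  "unassigned", .data$majority)) |>
      dplyr::select("cluster", "call", "agreement")
  }
  out
}
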