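#' RNA quality metrics and outlier filtering
#'
#' Outlier cells are defined by strict inequalities — UMI count below
#' `umi_min`, genes expressed below `genes_min`, or percent mitochondrial
#' counts above `mito_max` — so cells sitting exactly on a boundary are
#' retained. Mitochondrial features are identified by a name prefix.
#'
#' @param rna Cells x genes raw counts (sparse) with dimnames.
#' @param umi_min,genes_min,mito_max Thresholds (defaults 5000, 2000, 25).
#' @param mito_prefix Prefix marking mitochondrial features (default "MT-").
#' @return A list with `counts` (the kept cells), `qc` (per-cell tibble:
#'   `cell`, `umi_count`, `n_genes_expressed`, `pct_mito`, `keep`) and
#'   `removed` (named removal counts per criterion).
#' @export
rna_qc_filter <- function(rna, umi_min = 5000, genes_min = 2000, mito_max = 25,
                          mito_prefix = "MT-") {
  stopifnot(!is.null(rownames(rna)), !is.null(colnames(rna)))
  umi <- Matrix::rowSums(rna)
  ngene <- Matrix::rowSums(rna > 0)
  mito_cols <- startsWith(colnames(rna), mito_prefix)
  mito <- if (any(mito_cols)) {
    100 * Matrix::rowSums(rna[, mito_cols, drop = FALSE]) / pmax(umi, 1)
  } else {
    rep(0, nrow(rna))
  }
  low_umi <- umi < umi_min
  low_genes <- ngene < genes_min
  high_mito <- mito > mito_max
  keep <- !(low_umi | low_genes | high_mito)
  removed <- c(low_umi = sum(low_umi), low_genes = sum(low_genes),
               high_mito = sum(high_mito), total = sum(!keep))
  if (!any(keep)) {
    stop("no cells survive RNA QC (removed: ",
         paste(names(removed), removed, sep = "=", collapse = ", "), ")")
  }
  qc <- tibble::tibble(
    cell = rownames(rna),
    umi_count = as.integer(umi),
    n_genes_expressed = as.integer(ngene),
    pct_mito = as.numeric(mito),
    keep = keep
  )
  list(counts = rna[keep, , drop = FALSE], qc = qc, removed = removed)
}

#' Mixture-model threshold on log10 fragment counts
#'
#' Fits a two-component univariate Gaussian mixture by EM and returns the
#' point between the two component means where the posterior responsibility
#' flips (the solution of equal weighted densities). When the fit is
#' degenerate — one component takes less than `min_weight` of the data, or
#' the means are closer than `min_separation` — the configured `floor` is
#' returned
#' instead.
#'
#' @param log10_fragments Numeric vector (>= 50 finite values).
#' @param floor Fallback cutoff for degenerate fits (default 3).
#' @param min_weight Minimum component weight for a valid fit (default 0.05).
#' @param min_separation Minimum distance between component means, in log10
#'   units, for the fit to count as bimodal (default 0.5).
#' @param seed Seed for the EM initialisation.
#' @return A single numeric cutoff.
#' @export
gmm_depth_threshold <- function(log10_fragments, floor = 3, min_weight = 0.05,
                                min_separation = 0.5, seed = 1L) {
  x <- log10_fragments
  if (any(!is.finite(x))) stop("non-finite values in log10_fragments")
  if (length(x) < 50) stop("need at least 50 values to fit the mixture")
  withr::local_seed(seed)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this symbol in the caller
  fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) return(floor)
  mu <- fit$parameters$mean
  sd <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd) == 1) sd <- rep(sd, 2)
  w <- fit$parameters$pro
  if (min(w) < min_weight || abs(diff(mu)) < min_separation) return(floor)
  lo <- min(mu); hi <- max(mu)
  f <- function(t) {
    w[1] * stats::dnorm(t, mu[1], sd[1]) - w[2] * stats::dnorm(t, mu[2], sd[2])
  }
  # responsibilities flip where the weighted densities cross between the means
  if (sign(f(lo)) == sign(f(hi))) return(mean(c(lo, hi)))
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-8)$root
}

#' TSS enrichment proxy from tile counts and filtering
#'
#' The score of a cell is the mean count over tiles overlapping a TSS (plus
#' one tile on each side) divided by the mean count over flanking tiles
#' (offsets `flank_offsets` tiles away), stabilised with a small pseudocount
#' in the denominator. Cells are kept when `log10(score + 1) >= threshold`.
#'
#' @param atac Cells x tiles counts with `chrom:start-end` tile ids.
#' @param genes A gene-model tibble.
#' @param threshold_log10 Keep threshold on `log10(score + 1)` (default 0.9).
#' @param flank_offsets Tile offsets (in tiles) defining the flank window
#'   (default 2:5 on each side).
#' @param pseudocount Denominator stabiliser (default 0.01).
#' @return A list with `scores` (tibble: `cell`, `tss_score`,
#'   `log10_score`, `keep`) and `counts` (kept cells).
#' @export
tss_filter <- function(atac, genes, threshold_log10 = 0.9,
                       flank_offsets = 2:5, pseudocount = 0.01) {
  tiles <- parse_feature_intervals(colnames(atac))
  genes <- gene_models(genes)
  width <- unique(tiles$end - tiles$start)
  if (length(width) != 1) stop("tiles are not fixed width")
  key <- paste0(tiles$chrom, ":", tiles$start)
  tss_tile_start <- (genes$tss %/% width) * width
  tss_keys <- unlist(lapply(c(-width, 0L, width), function(off) {
    paste0(genes$chrom, ":", tss_tile_start + off)
  }))
  tss_idx <- which(key %in% tss_keys)
  if (length(tss_idx) == 0) stop("no tiles overlap any TSS window")
  flank_keys <- unlist(lapply(c(-flank_offsets, flank_offsets) * width, function(off) {
    paste0(genes$chrom, ":", tss_tile_start + off)
  }))
  flank_idx <- setdiff(which(key %in% flank_keys), tss_idx)
  if (length(flank_idx) == 0) stop("no flanking tiles available")
  mean_tss <- Matrix::rowMeans(atac[, tss_idx, drop = FALSE])
  mean_flank <- Matrix::rowMeans(atac[, flank_idx, drop = FALSE])
  score <- mean_tss / (mean_flank + pseudocount)
  keep <- log10(score + 1) >= threshold_log10
  scores <- tibble::tibble(
    cell = rownames(atac),
    tss_score = as.numeric(score),
    log10_score = log10(as.numeric(score) + 1),
    keep = keep
  )
  list(scores = scores, counts = atac[keep, , drop = FALSE])
}

#' Simulated-doublet nearest-neighbor scores
#'
#' Simulates `n_sim` artificial doublets by averaging the count profiles of
#' random cell pairs, embeds observed cells and simulated doublets together
#' (PCA on log-normalized counts, or TF-IDF/SVD for tiles), and scores each
#' observed cell by the fraction of simulated doublets among its `k` nearest
#' neighbors in that space.
#'
#' @param counts Cells x features raw counts (sparse).
#' @param n_sim Number of simulated doublets (default = number of cells).
#' @param k Neighborhood size (default 10).
#' @param dims Embedding dimensions (default 20).
#' @param modality `"rna"` (log-normalize + PCA) or `"atac"` (TF-IDF + SVD).
#' @param seed Seed for pair sampling and the solver.
#' @return A tibble with `cell` and `doublet_score`.
#' @export
doublet_scores <- function(counts, n_sim = nrow(counts), k = 10, dims = 20,
                           modality = c("rna", "atac"), seed = 1L) {
  modality <- match.arg(modality)
  n <- nrow(counts)
  if (k >= n) stop("k must be smaller than the number of cells")
  withr::local_seed(seed)
  i1 <- sample.int(n, n_sim, replace = TRUE)
  i2 <- sample.int(n, n_sim, replace = TRUE)
  resample <- which(i1 == i2)
  while (length(resample) > 0) {
    i2[resample] <- sample.int(n, length(resample), replace = TRUE)
    resample <- which(i1 == i2)
  }
  sim <- (counts[i1, , drop = FALSE] + counts[i2, , drop = FALSE])
  rownames(sim) <- paste0("sim-doublet-", seq_len(n_sim))
  all_counts <- rbind(counts, sim)
  if (modality == "rna") {
    norm <- log_normalize(all_counts)
    hv <- select_hvg(all_counts, n_top = min(1000, ncol(all_counts)))
    emb <- run_pca(scale_and_regress(norm[, hv, drop = FALSE]),
                   n = dims, seed = seed)$embedding
  } else {
    w <- tfidf(all_counts)
    emb <- svd_embed(w, dims = dims, seed = seed)$embedding
  }
  nn <- RANN::nn2(emb, emb[seq_len(n), , drop = FALSE], k = k + 1)$nn.idx
  nn <- nn[, -1, drop = FALSE]  # drop self
  score <- rowMeans(nn > n)
  tibble::tibble(cell = rownames(counts), doublet_score = as.numeric(score))
}

#' Remove the expected number of highest-scoring doublets
#'
#' The removal count is `filter_ratio * expected doublets`, where the
#' expected doublet count grows quadratically with loading:
#' `rate_per_1000 * (n / 1000)^2` for `n` observed cells, capped at `n`.
#' Ties at the cutoff score are broken by cell name for determinism.
#'
#' @param scores Tibble from [doublet_scores()].
#' @param filter_ratio Multiplier on the expected doublet count (default 1.0;
#'   0 removes nothing).
#' @param rate_per_1000 Expected doublets per 1000 cells (default 8).
#' @return `scores` with a logical `keep` column.
#' @export
doublet_filter <- function(scores, filter_ratio = 1.0, rate_per_1000 = 8) {
  n <- nrow(scores)
  expected <- rate_per_1000 * n / 1000 * n / 1000
  n_remove <- min(n, floor(filter_ratio * expected))
  ord <- order(-scores$doublet_score, scores$cell)
  keep <- rep(TRUE, n)
  if (n_remove > 0) keep[ord[seq_len(n_remove)]] <- FALSE
  scores$keep <- keep
  scores
}
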