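#' Merge per-cluster peak lists by iterative overlap
#'
#' Keeps the best-scoring remaining peak, removes every peak overlapping it
#' (1 bp or more), and repeats until no peaks remain — the standard way to
#' build a universal fixed-width peak set from per-cluster calls without
#' altering peak widths. Ties are broken by (chrom, start) for determinism.
#'
#' @param peaks An interval tibble with a numeric `score` column (higher is
#'   better); typically the concatenation of per-cluster peak calls.
#' @param fixed_width Optional width every peak must have (default NULL, no
#'   check).
#' @return The retained peaks as a sorted interval tibble.
#' @export
iterative_overlap_merge <- function(peaks, fixed_width = NULL) {
  # duplicated coordinates across clusters are expected; re-id before validating
  peaks$id <- NULL
  peaks$id <- paste0("input_", seq_len(nrow(peaks)))
  peaks <- genomic_intervals(peaks, fixed_width = fixed_width)
  if (nrow(peaks) == 0) return(peaks)
  if (any(is.na(peaks$score))) stop("every peak needs a score")
  ord <- order(-peaks$score, peaks$chrom, peaks$start, peaks$end)
  alive <- rep(TRUE, nrow(peaks))
  kept <- logical(nrow(peaks))
  # overlap adjacency once, then sweep in score order
  ov <- find_overlaps(peaks, peaks, min_overlap = 1)
  idx <- match(ov$id_a, peaks$id)
  jdx <- match(ov$id_b, peaks$id)
  nb <- split(jdx, idx)
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[nb[[as.character(i)]]] <- FALSE
  }
  out <- peaks[kept, , drop = FALSE]
  out$id <- paste0(out$chrom, ":", out$start, "-", out$end)
  genomic_intervals(out)
}

#' Classify peaks relative to gene annotation
#'
#' Priority promoter > exonic > intronic > distal. The promoter window is
#' `promoter_window` around the TSS, strand-aware (negative values are
#' upstream). A peak overlapping a gene body outside any promoter window is
#' intronic unless an exon set is supplied and it overlaps an exon. Distal
#' peaks touch neither a promoter window nor a gene body.
#'
#' @param peaks An interval tibble.
#' @param genes A gene-model tibble.
#' @param promoter_window Length-2 integer vector around the TSS (default
#'   `c(-2000, 100)`).
#' @param exons Optional interval tibble of exons; without it no peak is
#'   called exonic.
#' @return `peaks` with a `peak_class` column in
#'   {promoter, exonic, intronic, distal}.
#' @export
annotate_peaks <- function(peaks, genes, promoter_window = c(-2000L, 100L),
                           exons = NULL) {
  peaks <- genomic_intervals(peaks)
  genes <- gene_models(genes)
  prom_start <- ifelse(genes$strand == "+",
                       genes$tss + promoter_window[1],
                       genes$tss - promoter_window[2] + 1L)
  prom_end <- ifelse(genes$strand == "+",
                     genes$tss + promoter_window[2] + 1L,
                     genes$tss - promoter_window[1] + 1L)
  prom <- genomic_intervals(tibble::tibble(
    chrom = genes$chrom, start = pmax(prom_start, 0L), end = prom_end,
    id = paste0("prom_", genes$gene_id)
  ))
  body <- genomic_intervals(tibble::tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    id = paste0("body_", genes$gene_id)
  ))
  cls <- rep("distal", nrow(peaks))
  in_body <- peaks$id %in% find_overlaps(peaks, body)$id_a
  cls[in_body] <- "intronic"
  if (!is.null(exons) && nrow(exons) > 0) {
    in_exon <- peaks$id %in% find_overlaps(peaks, genomic_intervals(exons))$id_a
    cls[in_exon] <- "exonic"
  }
  in_prom <- peaks$id %in% find_overlaps(peaks, prom)$id_a
  cls[in_prom] <- "promoter"
  peaks$peak_class <- cls
  peaks
}

#' Low-overlap metacell groups by nearest neighbors
#'
#' Seed cells are chosen by farthest-point sampling in the reduced space;
#' each candidate group is the seed's `k` nearest cells (seed included), and
#' a group is accepted only when it shares at most `max_shared` cells with
#' every previously accepted group. Sampling stops at `n_groups` accepted
#' groups or when candidates are exhausted.
#'
#' @param reduced A `reduced_space` or a cells x dims matrix.
#' @param k Cells per group (default 100).
#' @param max_shared Maximum pairwise shared cells (default `0.8 * k`).
#' @param n_groups Target number of groups (default `ceiling(n / 20)`,
#'   capped at 500).
#' @param dims Retained dimensions to use (default all).
#' @param seed Seed for the first farthest-point pick.
#' @return A `metacell_grouping`: list with `groups` (list of integer cell
#'   index vectors), `cells` (the cell names indexed) and `k`.
#' @export
make_metacells <- function(reduced, k = 100, max_shared = floor(0.8 * k),
                           n_groups = NULL, dims = NULL, seed = 1L) {
  emb <- if (inherits(reduced, "reduced_space")) reduced_embedding(reduced, dims) else reduced
  n <- nrow(emb)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")")
  if (is.null(n_groups)) n_groups <- min(500L, ceiling(n / 20))
  withr::local_seed(seed)
  n_seeds <- n
  first <- sample.int(n, 1)
  min_dist <- sqrt(colSums((t(emb) - emb[first, ])^2))
  order_seeds <- integer(n_seeds)
  order_seeds[1] <- first
  if (n_seeds > 1) {
    for (s in 2:n_seeds) {
      nxt <- which.max(min_dist)
      order_seeds[s] <- nxt
      d <- sqrt(colSums((t(emb) - emb[nxt, ])^2))
      min_dist <- pmin(min_dist, d)
    }
  }
  nn <- RANN::nn2(emb, emb[order_seeds, , drop = FALSE], k = k)$nn.idx
  accepted <- list()
  for (s in seq_len(n_seeds)) {
    cand <- nn[s, ]
    ok <- TRUE
    for (g in accepted) {
      if (length(intersect(cand, g)) > max_shared) { ok <- FALSE; break }
    }
    if (ok) {
      accepted[[length(accepted) + 1]] <- sort(cand)
      if (length(accepted) >= n_groups) break
    }
  }
  cells <- rownames(emb)
  if (is.null(cells)) cells <- as.character(seq_len(n))
  structure(list(groups = accepted, cells = cells, k = k,
                 max_shared = max_shared),
            class = "metacell_grouping")
}

#' @noRd
#' @exportS3Method base::print
print.metacell_grouping <- function(x, ...) {
  cat(sprintf("<metacell_grouping> %d groups of %d cells (max shared %d) over %d cells\n",
              length(x$groups), x$k, x$max_shared, length(x$cells)))
  invisible(x)
}

#' Aggregate a cell-level matrix over metacell groups
#'
#' Sums each group's rows, then optionally depth-normalizes the sums with the
#' log-normalize transform (`normalize = "lognorm"`, the default, for raw
#' counts) or averages instead of summing (`normalize = "mean"`, for already
#' normalized or imputed values).
#'
#' @param x Cells x features matrix; rownames must cover the grouping's
#'   cells.
#' @param grouping A `metacell_grouping`.
#' @param normalize One of `"lognorm"`, `"mean"`, `"sum"`.
#' @return A metacells x features matrix (rows `metacell_1`, ...).
#' @export
aggregate_metacells <- function(x, grouping,
                                normalize = c("lognorm", "mean", "sum")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(grouping, "metacell_grouping"))
  idx <- match(grouping$cells, rownames(x))
  if (anyNA(idx)) stop("matrix lacks some grouping cells")
  g <- length(grouping$groups)
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(g), lengths(grouping$groups)),
    j = idx[unlist(grouping$groups)],
    x = 1,
    dims = c(g, nrow(x))
  )
  sums <- inc %*% x
  rownames(sums) <- paste0("metacell_", seq_len(g))
  colnames(sums) <- colnames(x)
  out <- switch(normalize,
    sum = sums,
    mean = sums / lengths(grouping$groups),
    lognorm = log_normalize(sums)
  )
  methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
}

#' Peak-to-gene correlation across metacells
#'
#' For every peak-gene pair on the same chromosome with `|distance| <=
#' max_dist` (signed distance from the peak midpoint to the TSS, positive
#' downstream of the gene), computes the Pearson correlation across
#' metacells, a two-sided p-value from the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))`, and Benjamini-Hochberg FDRs over all
#' tested pairs. Zero-variance peaks or genes are skipped and counted.
#'
#' @param atac_mc Metacells x peaks matrix (aggregated accessibility).
#' @param rna_mc Metacells x genes matrix (aggregated imputed expression),
#'   same rows as `atac_mc`.
#' @param peaks Interval tibble describing the peak columns (ids must match
#'   colnames of `atac_mc`); annotated with `peak_class` if not already.
#' @param genes Gene-model tibble for the gene columns.
#' @param max_dist Candidate window in bp (default 250000).
#' @param promoter_window Promoter window for peak classification.
#' @return A tibble of candidate links: `peak_id`, `gene_id`, `r`, `p`,
#'   `fdr`, `distance_bp`, `peak_class`; the number of skipped
#'   zero-variance pairs is in `attr(, "n_skipped")`.
#' @export
correlate_peak_gene <- function(atac_mc, rna_mc, peaks, genes,
                                max_dist = 250000,
                                promoter_window = c(-2000L, 100L)) {
  stopifnot(nrow(atac_mc) == nrow(rna_mc))
  n <- nrow(atac_mc)
  if (n < 3) stop("need at least 3 metacells")
  peaks <- genomic_intervals(peaks)
  if (!"peak_class" %in% names(peaks)) {
    peaks <- annotate_peaks(peaks, genes, promoter_window)
  }
  genes <- gene_models(genes)
  peaks <- peaks[peaks$id %in% colnames(atac_mc), , drop = FALSE]
  genes <- genes[genes$gene_id %in% colnames(rna_mc), , drop = FALSE]
  zp <- standardize_cols(as.matrix(atac_mc[, peaks$id, drop = FALSE]))
  zg <- standardize_cols(as.matrix(rna_mc[, genes$gene_id, drop = FALSE]))
  rows <- list()
  n_skipped <- 0L
  for (chrom in intersect(unique(peaks$chrom), unique(genes$chrom))) {
    pk <- peaks[peaks$chrom == chrom, , drop = FALSE]
    gn <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(pk) == 0 || nrow(gn) == 0) next
    mid <- (pk$start + pk$end) %/% 2L
    dist_mat <- outer(mid, gn$tss, "-")
    dist_mat <- sweep(dist_mat, 2, ifelse(gn$strand == "+", 1L, -1L), "*")
    cand <- which(abs(dist_mat) <= max_dist, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    rmat <- crossprod(zp[, pk$id, drop = FALSE], zg[, gn$gene_id, drop = FALSE]) / (n - 1)
    rvals <- rmat[cand]
    skip <- is.na(rvals)
    n_skipped <- n_skipped + sum(skip)
    cand <- cand[!skip, , drop = FALSE]
    rvals <- rvals[!skip]
    rows[[chrom]] <- tibble::tibble(
      peak_id = pk$id[cand[, 1]],
      gene_id = gn$gene_id[cand[, 2]],
      r = rvals,
      distance_bp = dist_mat[cand],
      peak_class = pk$peak_class[cand[, 1]]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(peak_id = character(), gene_id = character(),
                          r = numeric(), p = numeric(), fdr = numeric(),
                          distance_bp = integer(), peak_class = character())
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  r_clamped <- pmin(pmax(out$r, -1 + 1e-15), 1 - 1e-15)
  tval <- r_clamped * sqrt((n - 2) / (1 - r_clamped^2))
  out$p <- 2 * stats::pt(-abs(tval), df = n - 2)
  out$fdr <- benjamini_hochberg(out$p)
  out <- out[, c("peak_id", "gene_id", "r", "p", "fdr", "distance_bp", "peak_class")]
  out <- out[order(out$peak_id, out$gene_id), , drop = FALSE]
  attr(out, "n_skipped") <- n_skipped
  out
}

standardize_cols <- function(m) {
  mu <- colMeans(m)
  m <- sweep(m, 2, mu, "-")
  sds <- sqrt(colSums(m^2) / (nrow(m) - 1))
  sds[sds == 0] <- NA_real_
  sweep(m, 2, sds, "/")
}

#' Filter candidate links to the reported set
#'
#' Strict application of the headline thresholds: correlation at least `r_min`,
#' `fdr <= fdr_max` and membership of `peak_class` in `classes`.
#'
#' @param links Candidate link tibble from [correlate_peak_gene()].
#' @param r_min Correlation threshold, inclusive (default 0.45).
#' @param fdr_max FDR threshold, inclusive (default 1e-12).
#' @param classes Peak classes kept (default "distal").
#' @return The filtered tibble; `attr(, "summary")` holds the link count and
#'   number of unique peaks.
#' @export
filter_links <- function(links, r_min = 0.45, fdr_max = 1e-12,
                         classes = "distal") {
  out <- links[links$r >= r_min & links$fdr <= fdr_max &
                 links$peak_class %in% classes, , drop = FALSE]
  attr(out, "summary") <- list(n_links = nrow(out),
                               n_unique_peaks = length(unique(out$peak_id)))
  out
}

#' Mean profile per cell-type cluster
#'
#' @param x Cells x features matrix.
#' @param labels Named per-cell labels (names = rownames of `x`), or an
#'   unnamed vector aligned with the rows.
#' @return A types x features dense matrix.
#' @export
celltype_means <- function(x, labels) {
  if (!is.null(names(labels))) labels <- labels[rownames(x)]
  stopifnot(length(labels) == nrow(x))
  types <- sort(unique(labels))
  out <- t(vapply(types, function(tp) {
    Matrix::colMeans(x[labels == tp, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(out) <- types
  out
}

#' K-means clustering of filtered links
#'
#' Each link's feature vector concatenates the row-scaled per-cell-type mean
#' accessibility of its peak and the row-scaled per-cell-type mean expression
#' of its gene; links are clustered with Lloyd's algorithm (best of `n_init`
#' seeded starts by within-cluster sum of squares). Each cluster is labelled
#' with the cell type of its maximal mean feature.
#'
#' @param links Filtered link tibble.
#' @param peak_profiles Types x peaks matrix (e.g. [celltype_means()] of
#'   normalized accessibility).
#' @param gene_profiles Types x genes matrix of mean expression.
#' @param k Number of clusters (default 5).
#' @param n_init Number of seeded restarts (default 10).
#' @param seed Seed.
#' @return `links` with a `kmeans_cluster` column; `attr(, "cluster_labels")`
#'   is a tibble mapping cluster to its enriched cell type.
#' @export
kmeans_links <- function(links, peak_profiles, gene_profiles, k = 5,
                         n_init = 10, seed = 1L) {
  if (nrow(links) == 0) {
    links$kmeans_cluster <- integer(0)
    return(links)
  }
  stopifnot(identical(rownames(peak_profiles), rownames(gene_profiles)))
  row_scale <- function(m) {
    mu <- rowMeans(m)
    sds <- apply(m, 1, stats::sd)
    sds[sds == 0] <- 1
    (m - mu) / sds
  }
  acc <- row_scale(t(peak_profiles[, links$peak_id, drop = FALSE]))
  expr <- row_scale(t(gene_profiles[, links$gene_id, drop = FALSE]))
  feats <- cbind(acc, expr)
  k_eff <- min(k, nrow(unique(as.data.frame(feats))))
  withr::local_seed(seed)
  km <- withCallingHandlers(
    stats::kmeans(feats, centers = k_eff, nstart = n_init,
                  algorithm = "Lloyd", iter.max = 200),
    warning = function(w) {
      # empty clusters in individual Lloyd restarts are expected; nstart
      # keeps the best non-degenerate solution
      if (grepl("empty cluster", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  # relabel clusters by decreasing size for stability
  sizes <- sort(table(km$cluster), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  links$kmeans_cluster <- as.integer(relabel[as.character(km$cluster)])
  types <- rownames(peak_profiles)
  centers <- km$centers[as.integer(names(sizes)), , drop = FALSE]
  type_score <- centers[, seq_along(types), drop = FALSE] +
    centers[, length(types) + seq_along(types), drop = FALSE]
  lab <- types[max.col(type_score, ties.method = "first")]
  attr(links, "cluster_labels") <- tibble::tibble(
    kmeans_cluster = seq_len(k_eff), celltype = lab
  )
  links
}
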