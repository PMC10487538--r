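#' Depth-normalized log expression
#'
#' `x' = ln(1 + scale * x / cell_total)` per cell, the standard log-normalize
#' transform. Cells with zero total are rejected (filter them upstream).
#'
#' @param counts Cells x features sparse or dense non-negative matrix.
#' @param scale Size-factor target (default 1e4).
#' @return A sparse cells x features matrix of normalized values.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    stop(sum(totals == 0), " cell(s) have zero total counts; remove them before normalizing")
  }
  out <- counts
  # CSC storage: recover the row (cell) of every nonzero to scale by its total
  rows <- out@i + 1L
  out@x <- log1p(scale * out@x / totals[rows])
  out
}

#' Highly variable gene selection by standardized variance
#'
#' The "vst"-style selection: per gene, expected standard deviation is taken
#' from a degree-2 polynomial fit of log10(variance) on log10(mean) across
#' genes; counts are standardized with that expectation, clipped at sqrt(n),
#' and genes are ranked by the variance of the clipped values. Ties are
#' broken by gene id.
#'
#' @param counts Cells x genes raw counts (sparse).
#' @param n_top Number of genes to select (default 2000).
#' @return Character vector of `n_top` gene ids, most variable first.
#' @export
select_hvg <- function(counts, n_top = 2000) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  n_genes <- ncol(counts)
  if (n_top > n_genes) stop("n_top (", n_top, ") exceeds number of genes (", n_genes, ")")
  n <- nrow(counts)
  mu <- Matrix::colMeans(counts)
  ex2 <- Matrix::colMeans(counts^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  ok <- v > 0 & mu > 0
  fit_df <- data.frame(lv = log10(v[ok]), lm = log10(mu[ok]))
  fit <- stats::lm(lv ~ stats::poly(lm, degree = min(2, max(1, sum(ok) - 1)), raw = TRUE),
                   data = fit_df)
  sd_exp <- rep(NA_real_, n_genes)
  sd_exp[ok] <- sqrt(10^stats::predict(fit, newdata = fit_df))
  clip <- sqrt(n)
  # variance of clipped standardized values, computed from the sparse triplet
  sv <- numeric(n_genes)
  j_idx <- rep(seq_len(n_genes), diff(counts@p))
  x <- counts@x
  z_nz <- pmin(pmax((x - mu[j_idx]) / sd_exp[j_idx], -clip), clip)
  z0 <- pmin(pmax((0 - mu) / sd_exp, -clip), clip)
  nnz <- diff(counts@p)
  s1 <- as.numeric(tapply(z_nz, factor(j_idx, levels = seq_len(n_genes)), sum, default = 0))
  s2 <- as.numeric(tapply(z_nz^2, factor(j_idx, levels = seq_len(n_genes)), sum, default = 0))
  s1 <- s1 + (n - nnz) * z0
  s2 <- s2 + (n - nnz) * z0^2
  sv[ok] <- ((s2 - s1^2 / n) / (n - 1))[ok]
  sv[!ok] <- 0
  ids <- colnames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(n_genes))
  ids[order(-sv, ids)][seq_len(n_top)]
}

#' Scale expression with optional covariate regression
#'
#' Per gene: residuals of an ordinary least-squares fit on the covariate
#' (with intercept), then z-scored and clipped at +/- `clip`. With no
#' covariate this reduces to centering and scaling.
#'
#' @param normalized Cells x genes matrix of normalized expression.
#' @param covariate Optional numeric per-cell covariate (e.g. percent
#'   mitochondrial counts) to regress out.
#' @param clip Clipping bound on the z-scores (default 10).
#' @return A dense cells x genes matrix of scaled residuals.
#' @export
scale_and_regress <- function(normalized, covariate = NULL, clip = 10) {
  y <- as.matrix(normalized)
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == nrow(y))
    x <- cbind(1, as.numeric(covariate))
    beta <- solve(crossprod(x), crossprod(x, y))
    y <- y - x %*% beta
  } else {
    y <- sweep(y, 2, colMeans(y), "-")
  }
  sds <- sqrt(colSums(y^2) / (nrow(y) - 1))
  sds[sds < 1e-10] <- 1  # residuals that are numerically zero stay zero
  y <- sweep(y, 2, sds, "/")
  y[y > clip] <- clip
  y[y < -clip] <- -clip
  y
}

new_reduced_space <- function(embedding, loadings, method, sdev,
                              depth = NULL, cor_cutoff = NULL) {
  depth_correlation <- rep(NA_real_, ncol(embedding))
  retained <- seq_len(ncol(embedding))
  if (!is.null(depth)) {
    depth_correlation <- as.numeric(stats::cor(embedding, depth))
    if (!is.null(cor_cutoff)) {
      retained <- which(abs(depth_correlation) <= cor_cutoff)
    }
  }
  structure(
    list(embedding = embedding, loadings = loadings, method = method,
         sdev = sdev, depth_correlation = depth_correlation,
         retained_dims = retained),
    class = "reduced_space"
  )
}

#' @noRd
#' @exportS3Method base::print
print.reduced_space <- function(x, ...) {
  cat(sprintf("<reduced_space> %s: %d cells x %d dims (%d retained)\n",
              x$method, nrow(x$embedding), ncol(x$embedding),
              length(x$retained_dims)))
  invisible(x)
}

#' Extract the retained embedding of a reduced space
#'
#' @param reduced A `reduced_space` from [run_pca()] or [iterative_lsi()].
#' @param dims How many of the retained dimensions to keep (default all).
#' @return A cells x dims matrix.
#' @export
reduced_embedding <- function(reduced, dims = NULL) {
  stopifnot(inherits(reduced, "reduced_space"))
  keep <- reduced$retained_dims
  if (!is.null(dims)) keep <- keep[seq_len(min(dims, length(keep)))]
  reduced$embedding[, keep, drop = FALSE]
}

#' Principal component analysis of scaled expression
#'
#' Deterministic sign convention: within each component the loading of
#' largest magnitude is made positive.
#'
#' @param scaled Dense cells x genes matrix from [scale_and_regress()].
#' @param n Number of components (default 50).
#' @param seed Seed for the truncated solver.
#' @return A `reduced_space` with `embedding`, gene `loadings` and `sdev`.
#' @export
run_pca <- function(scaled, n = 50, seed = 1L) {
  n <- min(n, ncol(scaled) - 1L, nrow(scaled) - 1L)
  withr::local_seed(seed)
  centered <- sweep(scaled, 2, colMeans(scaled), "-")
  sv <- irlba::irlba(centered, nv = n, nu = n)
  flip <- vapply(seq_len(n), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v, 2, flip, "*")
  emb <- sweep(sv$u %*% diag(sv$d, n, n), 2, flip, "*")
  rownames(emb) <- rownames(scaled)
  rownames(loadings) <- colnames(scaled)
  colnames(emb) <- colnames(loadings) <- paste0("PC", seq_len(n))
  new_reduced_space(emb, loadings, "pca", sdev = sv$d / sqrt(nrow(scaled) - 1))
}

#' Term frequency-inverse document frequency weighting of tile counts
#'
#' `log(1 + tf * idf * scale)` with `tf = count / cell_total` and
#' `idf = n_cells / n_cells_with_feature`. Tiles observed in no cell get
#' weight zero.
#'
#' @param tiles Cells x tiles counts (sparse); binarized first when
#'   `binarize = TRUE` (default).
#' @param scale Scale constant inside the log (default 1e4).
#' @param binarize Reduce counts to presence/absence first?
#' @return A sparse cells x tiles weighted matrix.
#' @export
tfidf <- function(tiles, scale = 1e4, binarize = TRUE) {
  x <- methods::as(methods::as(tiles, "CsparseMatrix"), "generalMatrix")
  if (binarize) x@x <- as.numeric(x@x > 0)
  totals <- Matrix::rowSums(x)
  if (any(totals == 0)) stop("cells with zero accessible tiles; filter first")
  df <- Matrix::colSums(x > 0)
  idf <- ifelse(df > 0, nrow(x) / df, 0)
  rows <- x@i + 1L
  cols <- rep(seq_len(ncol(x)), diff(x@p))
  x@x <- log1p((x@x / totals[rows]) * idf[cols] * scale)
  x
}

svd_embed <- function(mat, dims, seed) {
  withr::local_seed(seed)
  sv <- irlba::irlba(mat, nv = dims, nu = dims)
  flip <- vapply(seq_len(dims), function(j) {
    v <- sv$v[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  emb <- sweep(sv$u %*% diag(sv$d, dims, dims), 2, flip, "*")
  rownames(emb) <- rownames(mat)
  colnames(emb) <- paste0("LSI", seq_len(dims))
  list(embedding = emb, loadings = sweep(sv$v, 2, flip, "*"), d = sv$d)
}

#' Iterative latent semantic indexing of a tile matrix
#'
#' Two-round TF-IDF + truncated SVD. Round 1 uses the `n_var` most accessible
#' tiles and produces coarse k-means clusters; round 2 re-selects the `n_var`
#' tiles most variable across the round-1 cluster pseudobulks and recomputes
#' the decomposition. Dimensions whose correlation with log10 sequencing
#' depth exceeds `cor_cutoff` in magnitude are excluded from the retained
#' set.
#'
#' @param tiles Cells x tiles counts (sparse).
#' @param n_var Number of variable tiles per iteration (default 25000; when
#'   fewer tiles exist, all are used with a warning).
#' @param n_iter Number of LSI iterations (default 2).
#' @param dims Number of SVD dimensions (default 30).
#' @param cor_cutoff Depth-correlation cutoff for retaining dimensions
#'   (default 0.75).
#' @param coarse_k Number of coarse clusters between iterations (default 6).
#' @param binarize Binarize tile counts (default TRUE)?
#' @param seed Seed controlling the solver and coarse clustering.
#' @return A `reduced_space` with per-dimension `depth_correlation` and
#'   `retained_dims`.
#' @export
iterative_lsi <- function(tiles, n_var = 25000, n_iter = 2, dims = 30,
                          cor_cutoff = 0.75, coarse_k = 6, binarize = TRUE,
                          seed = 1L) {
  tiles <- methods::as(methods::as(tiles, "CsparseMatrix"), "generalMatrix")
  if (n_var > ncol(tiles)) {
    warning("n_var exceeds the number of tiles; using all ", ncol(tiles), " tiles")
    n_var <- ncol(tiles)
  }
  depth <- log10(Matrix::rowSums(tiles) + 1)
  bin <- tiles
  if (binarize) bin@x <- as.numeric(bin@x > 0)
  accessibility <- Matrix::colSums(bin)
  feat <- order(-accessibility)[seq_len(n_var)]
  res <- NULL
  for (iter in seq_len(n_iter)) {
    w <- tfidf(tiles[, feat, drop = FALSE], binarize = binarize)
    dec <- svd_embed(w, dims, seed = seed + iter)
    keep <- which(abs(as.numeric(stats::cor(dec$embedding, depth))) <= cor_cutoff)
    if (length(keep) == 0) keep <- seq_len(dims)[-1]
    if (iter < n_iter) {
      withr::local_seed(seed + 100L + iter)
      cl <- stats::kmeans(dec$embedding[, keep, drop = FALSE],
                          centers = min(coarse_k, nrow(tiles) - 1),
                          nstart = 5, iter.max = 50)$cluster
      # pseudobulk accessibility per coarse cluster, then most variable tiles
      groups <- sort(unique(cl))
      pb <- vapply(groups, function(g) {
        Matrix::colMeans(bin[cl == g, , drop = FALSE])
      }, numeric(ncol(bin)))
      lv <- log2(1e4 * sweep(pb, 2, colSums(pb) + 1e-12, "/") + 1)
      vars <- matrixStats_rowVars(lv)
      feat <- order(-vars)[seq_len(n_var)]
    }
    res <- dec
  }
  out <- new_reduced_space(res$embedding, res$loadings, "lsi",
                           sdev = res$d, depth = depth, cor_cutoff = cor_cutoff)
  out
}

# row variances without a matrixStats dependency
matrixStats_rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Graph-based clustering of cells in a reduced space
#'
#' Builds a shared-nearest-neighbor graph (Jaccard weights over the k-nearest
#' neighbor sets, pruned below `prune`) and partitions it with Louvain
#' modularity optimization at the requested resolution.
#'
#' @param reduced A `reduced_space`, or a plain cells x dims matrix.
#' @param k_nn Neighborhood size (default 20).
#' @param resolution Louvain resolution (default 0.8).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @param dims Number of retained dimensions to use (default all).
#' @param seed Seed for the community detection.
#' @return A tibble with columns `cell` and `cluster` (integer, 1-based,
#'   labelled in decreasing cluster size); the resolution is kept as an
#'   attribute.
#' @export
cluster_graph <- function(reduced, k_nn = 20, resolution = 0.8,
                          prune = 1 / 15, dims = NULL, seed = 1L) {
  emb <- if (inherits(reduced, "reduced_space")) reduced_embedding(reduced, dims) else reduced
  n <- nrow(emb)
  if (k_nn >= n) stop("k_nn must be smaller than the number of cells")
  nn <- RANN::nn2(emb, k = k_nn)$nn.idx
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k_nn), j = as.vector(nn), x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(adj)
  shared <- methods::as(shared, "TsparseMatrix")
  jac <- shared@x / (2 * k_nn - shared@x)
  keep <- jac >= prune & shared@i < shared@j
  g <- igraph::graph_from_data_frame(
    data.frame(from = shared@i[keep] + 1L, to = shared@j[keep] + 1L,
               weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  withr::local_seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)[as.character(seq_len(n))]
  # relabel clusters by decreasing size for stable downstream ids
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cells <- rownames(emb)
  if (is.null(cells)) cells <- as.character(seq_len(n))
  out <- tibble::tibble(cell = cells, cluster = as.integer(relabel[as.character(memb)]))
  attr(out, "resolution") <- resolution
  out
}

#' Remove per-batch location shifts in a reduced space
#'
#' Subtracts each batch's mean embedding and restores the global mean; a
#' deliberately simple stand-in for mixture-aligning batch integration.
#'
#' @param reduced A `reduced_space`.
#' @param batch Per-cell batch labels (length = number of cells).
#' @return The `reduced_space` with a centered embedding.
#' @export
batch_center <- function(reduced, batch) {
  stopifnot(inherits(reduced, "reduced_space"))
  emb <- reduced$embedding
  stopifnot(length(batch) == nrow(emb))
  global <- colMeans(emb)
  for (b in unique(batch)) {
    idx <- which(batch == b)
    emb[idx, ] <- sweep(emb[idx, , drop = FALSE], 2,
                        colMeans(emb[idx, , drop = FALSE]) - global, "-")
  }
  reduced$embedding <- emb
  reduced
}

#' Gene activity scores from tile accessibility
#'
#' For each gene, sums tile counts weighted by `exp(-d / decay_bp)`, where
#' `d` is the distance from the tile to the gene body extended upstream by
#' `promoter_ext` (0 for tiles overlapping the extended body, so those tiles
#' get weight 1). Tiles farther than `flank_bp` contribute nothing.
#'
#' @param tiles Cells x tiles counts with tile ids `chrom:start-end` as
#'   colnames (or supply `tile_intervals`).
#' @param genes A gene-model tibble.
#' @param promoter_ext Upstream promoter extension in bp (default 2000).
#' @param decay_bp Exponential decay constant in bp (default 5000).
#' @param flank_bp Maximum distance considered (default 25000).
#' @param tile_intervals Optional interval tibble describing the tile columns.
#' @return A sparse cells x genes score matrix.
#' @export
gene_activity <- function(tiles, genes, promoter_ext = 2000, decay_bp = 5000,
                          flank_bp = 25000, tile_intervals = NULL) {
  genes <- gene_models(genes)
  if (is.null(tile_intervals)) {
    tile_intervals <- parse_feature_intervals(colnames(tiles))
  }
  ext_start <- ifelse(genes$strand == "+", genes$start - promoter_ext, genes$start)
  ext_end <- ifelse(genes$strand == "+", genes$end, genes$end + promoter_ext)
  ext_start <- pmax(ext_start, 0L)
  reach <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(ext_start - flank_bp, 0L) + 1L, ext_end + flank_bp)
  )
  body <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(ext_start + 1L, ext_end))
  tg <- GenomicRanges::GRanges(tile_intervals$chrom,
                               IRanges::IRanges(tile_intervals$start + 1L, tile_intervals$end))
  hits <- GenomicRanges::findOverlaps(tg, reach)
  ti <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(tg[ti], body[gi])
  d[is.na(d)] <- 0L
  w <- exp(-as.numeric(d) / decay_bp)
  # each tile contributes to its nearest gene only, so one gene's strong
  # promoter cannot leak into a neighbor's activity score
  best <- order(ti, -w)
  keep <- !duplicated(ti[best])
  ti <- ti[best][keep]; gi <- gi[best][keep]; w <- w[best][keep]
  wmat <- Matrix::sparseMatrix(i = ti, j = gi, x = w,
                               dims = c(nrow(tile_intervals), nrow(genes)))
  out <- tiles %*% wmat
  colnames(out) <- genes$gene_id
  rownames(out) <- rownames(tiles)
  methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
}

#' Parse `chrom:start-end` feature ids into an interval tibble
#'
#' @param ids Character vector of feature ids in 0-based half-open
#'   `chrom:start-end` form.
#' @return An interval tibble in the same order as `ids` (unsorted).
#' @export
parse_feature_intervals <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- which(lengths(m) != 4)
  if (length(bad) > 0) stop("unparseable feature id: ", ids[bad[1]])
  tibble::tibble(
    chrom = vapply(m, `[[`, "", 2),
    start = as.integer(vapply(m, `[[`, "", 3)),
    end = as.integer(vapply(m, `[[`, "", 4)),
    id = ids
  )
}

#' Cross-modality label transfer by projection and nearest neighbors
#'
#' Projects the query cells (gene activity of ATAC cells) into the reference
#' PCA space using the reference gene loadings, then assigns each query cell
#' the majority label among its `k` nearest reference cells, with a
#' prediction score equal to the winning neighbor fraction. Cells scoring at
#' or below `min_score` are flagged for exclusion. The imputed expression of
#' a query cell is the uniform mean of its neighbors' normalized expression.
#'
#' @param ref_reduced A `reduced_space` from [run_pca()] on the reference.
#' @param ref_normalized Reference cells x genes normalized expression (for
#'   imputation).
#' @param ref_labels Named character vector: reference cell -> label.
#' @param query_activity Query cells x genes gene-activity matrix (raw
#'   scores; they are log-normalized and scaled internally).
#' @param k Neighborhood size for the label vote (default 15).
#' @param impute_k Neighborhood size for expression imputation (default
#'   `k`); smaller values keep the imputed expression field rougher, which
#'   preserves the effective degrees of freedom downstream correlations
#'   rely on.
#' @param min_score Exclusion threshold; score <= min_score is excluded
#'   (default 0.5).
#' @param dims Number of reference dimensions to use (default 30).
#' @param ref_samples,query_samples Optional per-cell sample labels; when
#'   both are given and `constrain_by_sample` is TRUE, neighbors are
#'   restricted to reference cells of the same sample.
#' @param constrain_by_sample Restrict neighbors to the same sample?
#' @return A list with `labels` (tibble: `cell`, `label`, `prediction_score`,
#'   `retained`) and `imputed` (query cells x genes dense matrix).
#' @export
label_transfer <- function(ref_reduced, ref_normalized, ref_labels,
                           query_activity, k = 15, impute_k = k,
                           min_score = 0.5,
                           dims = 30, ref_samples = NULL, query_samples = NULL,
                           constrain_by_sample = FALSE) {
  stopifnot(impute_k >= 1, impute_k <= k)
  stopifnot(inherits(ref_reduced, "reduced_space"))
  feats <- rownames(ref_reduced$loadings)
  missing_feats <- setdiff(feats, colnames(query_activity))
  if (length(missing_feats) > 0) {
    stop("query activity lacks ", length(missing_feats), " reference features")
  }
  dims <- min(dims, ncol(ref_reduced$embedding))
  qa <- log_normalize(query_activity[, feats, drop = FALSE] )
  qs <- scale_and_regress(qa)
  q_emb <- qs %*% ref_reduced$loadings[, seq_len(dims), drop = FALSE]
  r_emb <- ref_reduced$embedding[, seq_len(dims), drop = FALSE]
  ref_cells <- rownames(r_emb)
  query_cells <- rownames(q_emb)
  stopifnot(all(ref_cells %in% names(ref_labels)))
  if (constrain_by_sample) {
    stopifnot(!is.null(ref_samples), !is.null(query_samples))
    stopifnot(length(ref_samples) == nrow(r_emb), length(query_samples) == nrow(q_emb))
  }
  nbr <- matrix(0L, nrow(q_emb), k)
  if (constrain_by_sample) {
    for (s in unique(query_samples)) {
      qi <- which(query_samples == s)
      ri <- which(ref_samples == s)
      if (length(ri) == 0) stop("no reference cells for sample ", s)
      if (length(ri) < k) stop("fewer than k reference cells for sample ", s)
      nn <- RANN::nn2(r_emb[ri, , drop = FALSE], q_emb[qi, , drop = FALSE], k = k)$nn.idx
      nbr[qi, ] <- matrix(ri[nn], nrow = length(qi))
    }
  } else {
    if (nrow(r_emb) < k) stop("fewer than k reference cells")
    nbr[, ] <- RANN::nn2(r_emb, q_emb, k = k)$nn.idx
  }
  lab_mat <- matrix(ref_labels[ref_cells][nbr], nrow = nrow(nbr))
  winners <- apply(lab_mat, 1, function(r) {
    tab <- sort(table(r), decreasing = TRUE)
    # deterministic tie-break: alphabetical among the top counts
    top <- names(tab)[tab == tab[1]]
    c(sort(top)[1], tab[1])
  })
  label <- winners[1, ]
  score <- as.numeric(winners[2, ]) / k
  ref_norm <- methods::as(methods::as(ref_normalized, "CsparseMatrix"), "generalMatrix")
  nbr_imp <- nbr[, seq_len(impute_k), drop = FALSE]
  agg <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(nbr_imp)), impute_k), j = as.vector(nbr_imp),
    x = 1 / impute_k,
    dims = c(nrow(nbr_imp), nrow(ref_norm))
  )
  imputed <- as.matrix(agg %*% ref_norm)
  rownames(imputed) <- query_cells
  colnames(imputed) <- colnames(ref_norm)
  list(
    labels = tibble::tibble(
      cell = query_cells, label = label,
      prediction_score = score, retained = score > min_score
    ),
    imputed = imputed
  )
}

#' Per-cell marker module scores
#'
#' The mean normalized expression of each configured marker list, a simple
#' module-score stand-in used for cluster-majority cell typing.
#'
#' @param normalized Cells x genes normalized expression.
#' @param marker_sets Named list of marker gene vectors, one per cell type.
#' @return A tibble with `cell`, one score column per type, and `label`
#'   (argmax type).
#' @export
marker_scores <- function(normalized, marker_sets) {
  stopifnot(is.list(marker_sets), !is.null(names(marker_sets)))
  scores <- vapply(marker_sets, function(gs) {
    gs <- intersect(gs, colnames(normalized))
    if (length(gs) == 0) return(rep(0, nrow(normalized)))
    Matrix::rowMeans(normalized[, gs, drop = FALSE])
  }, numeric(nrow(normalized)))
  label <- colnames(scores)[max.col(scores, ties.method = "first")]
  out <- tibble::as_tibble(scores)
  out <- dplyr::bind_cols(tibble::tibble(cell = rownames(normalized)), out)
  out$label <- label
  out
}

#' Majority-vote cell types for clusters
#'
#' @param clusters Tibble with `cell` and `cluster` (from [cluster_graph()]).
#' @param cell_labels Named character vector: cell -> type label.
#' @return A tibble with `cluster`, `label` (majority type) and `purity`
#'   (majority fraction).
#' @export
assign_cluster_celltypes <- function(clusters, cell_labels) {
  stopifnot(all(c("cell", "cluster") %in% names(clusters)))
  clusters |>
    dplyr::mutate(type = unname(cell_labels[.data$cell])) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      label = names(sort(table(.data$type), decreasing = TRUE))[1],
      purity = max(table(.data$type)) / dplyr::n(),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster)
}

#' Drop low-quality or unassignable clusters
#'
#' A cluster is dropped when its mean RNA counts or mean ATAC fragment counts
#' fall below the thresholds, or its label is in the drop set. Boundary
#' values (mean exactly at the threshold) are kept.
#'
#' @param cluster_labels Tibble with `cluster` and `label` (from
#'   [assign_cluster_celltypes()]).
#' @param clusters Tibble with `cell`, `cluster`.
#' @param rna_counts Optional named per-cell RNA total counts.
#' @param atac_fragments Optional named per-cell ATAC fragment counts.
#' @param rna_mean_min,atac_frag_mean_min Mean-count thresholds (default
#'   5000; only applied when the corresponding counts are supplied).
#' @param drop_labels Labels to drop outright (default "unassigned").
#' @return The `cluster_labels` tibble with mean-count columns and a logical
#'   `kept`.
#' @export
filter_clusters <- function(cluster_labels, clusters, rna_counts = NULL,
                            atac_fragments = NULL, rna_mean_min = 5000,
                            atac_frag_mean_min = 5000,
                            drop_labels = "unassigned") {
  means_of <- function(v) {
    if (is.null(v)) return(rep(NA_real_, nrow(cluster_labels)))
    m <- clusters |>
      dplyr::mutate(val = unname(v[.data$cell])) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(mean_val = mean(.data$val, na.rm = TRUE), .groups = "drop")
    m$mean_val[match(cluster_labels$cluster, m$cluster)]
  }
  out <- cluster_labels
  out$mean_rna <- means_of(rna_counts)
  out$mean_atac <- means_of(atac_fragments)
  drop <- out$label %in% drop_labels
  if (!is.null(rna_counts)) drop <- drop | out$mean_rna < rna_mean_min
  if (!is.null(atac_fragments)) drop <- drop | out$mean_atac < atac_frag_mean_min
  out$kept <- !drop
  out
}
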