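toy_counts <- function(n = 30, g = 20, seed = 1, mu = 5) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * g, mu), n, g,
                dimnames = list(paste0("c", seq_len(n)), paste0("g", seq_len(g))))
  })
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("log normalization follows the closed form and is scale invariant", {
  m <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = c(10, 9990),
                            dims = c(1, 2),
                            dimnames = list("c1", c("g1", "g2")))
  norm <- log_normalize(m)
  expect_equal(norm[1, 1], log(11), tolerance = 1e-12)

  m2 <- toy_counts()
  doubled <- m2
  doubled[3, ] <- doubled[3, ] * 2
  expect_equal(as.numeric(log_normalize(m2)[3, ]),
               as.numeric(log_normalize(doubled)[3, ]), tolerance = 1e-12)
  zero <- m2; zero[1, ] <- 0
  expect_error(log_normalize(zero), "zero total")
})

test_that("variable-gene selection ignores constant genes and respects n_top", {
  m <- toy_counts(n = 50, g = 30, seed = 2)
  m[, 5] <- 3  # constant gene
  hv <- select_hvg(m, n_top = 10)
  expect_false("g5" %in% hv)
  all_genes <- select_hvg(m, n_top = 30)
  expect_setequal(all_genes, colnames(m))
  expect_error(select_hvg(m, n_top = 31), "exceeds")
})

test_that("planted bimodal marker genes rank at the top of the selection", {
  co <- small_cohort()
  hv <- select_hvg(co$rna, n_top = 400)
  markers <- unlist(co$marker_sets)
  expect_gt(mean(markers %in% hv), 0.9)
})

test_that("scaling with covariate regression matches the normal-equations oracle", {
  withr::with_seed(4, {
    y <- matrix(rnorm(200 * 8), 200, 8)
    covar <- rnorm(200)
    y[, 1] <- 2 * covar + 1  # exactly linear in the covariate
  })
  out <- scale_and_regress(y, covariate = covar)
  expect_true(all(abs(out[, 1]) < 1e-8))
  x <- cbind(1, covar)
  resid <- y - x %*% solve(crossprod(x), crossprod(x, y))
  resid <- scale(resid, center = FALSE,
                 scale = sqrt(colSums(scale(resid, scale = FALSE)^2) / 199))
  # column 1 is degenerate; compare the others
  expect_equal(out[, -1], pmin(pmax(resid[, -1], -10), 10), tolerance = 1e-8,
               ignore_attr = TRUE)
  centered <- scale_and_regress(y)
  expect_equal(colMeans(centered), rep(0, 8), tolerance = 1e-12)
})

test_that("PCA recovers rank-1 structure with orthogonal centered components", {
  withr::with_seed(6, {
    u <- rnorm(120); v <- rnorm(15)
    x <- outer(u, v) + matrix(rnorm(120 * 15, sd = 0.01), 120, 15)
  })
  rownames(x) <- paste0("c", 1:120)
  colnames(x) <- paste0("g", 1:15)
  p <- run_pca(x, n = 5, seed = 1)
  vars <- apply(p$embedding, 2, var)
  expect_gt(vars[1] / sum(vars), 0.99)
  expect_equal(crossprod(p$loadings)[1, 2], 0, tolerance = 1e-8)
  expect_equal(colMeans(p$embedding), rep(0, 5), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("TF-IDF gives identical rows for identical cells and LSI drops depth dims", {
  m <- toy_counts(n = 20, g = 50, seed = 8, mu = 2)
  m[2, ] <- m[1, ]
  w <- tfidf(m)
  expect_equal(as.numeric(w[1, ]), as.numeric(w[2, ]), tolerance = 1e-12)

  # depth-only variation: same profile, scaled depth per cell
  withr::with_seed(9, {
    base <- rpois(400, 3) + 1
    depth <- sample(1:20, 150, replace = TRUE)
    counts <- t(vapply(depth, function(d) rbinom(400, base * 3, d / 25),
                       numeric(400)))
  })
  rownames(counts) <- paste0("c", 1:150)
  colnames(counts) <- paste0("chr1:", (0:399) * 500, "-", (0:399) * 500 + 500)
  red <- iterative_lsi(Matrix::Matrix(counts, sparse = TRUE), n_var = 400,
                       dims = 6, seed = 1)
  dropped <- setdiff(seq_len(6), red$retained_dims)
  expect_true(length(dropped) >= 1)
  expect_true(all(abs(red$depth_correlation[dropped]) > 0.75))
  expect_warning(iterative_lsi(Matrix::Matrix(counts, sparse = TRUE),
                               n_var = 1000, dims = 4, seed = 1),
                 "using all")
})

test_that("graph clustering separates blobs and collapses at tiny resolution", {
  withr::with_seed(10, {
    emb <- rbind(matrix(rnorm(100 * 5), 100, 5),
                 matrix(rnorm(100 * 5, mean = 12), 100, 5))
  })
  rownames(emb) <- paste0("c", 1:200)
  cl <- cluster_graph(emb, k_nn = 15, resolution = 0.8, seed = 1)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[1:100])), 1)

  # on a connected cloud a tiny resolution collapses everything together
  withr::with_seed(11, cloud <- matrix(rnorm(150 * 5), 150, 5))
  rownames(cloud) <- paste0("d", 1:150)
  one <- cluster_graph(cloud, k_nn = 15, resolution = 1e-4, seed = 1)
  expect_equal(length(unique(one$cluster)), 1)

  # stability under permutation of cells, up to relabeling
  perm <- withr::with_seed(2, sample(200))
  cl2 <- cluster_graph(emb[perm, ], k_nn = 15, resolution = 0.8, seed = 1)
  joined <- dplyr::inner_join(cl, cl2, by = "cell")
  tab <- table(joined$cluster.x, joined$cluster.y)
  expect_equal(sum(apply(tab, 1, max)), 200)
  expect_error(cluster_graph(emb, k_nn = 300), "smaller")
})

test_that("batch centering removes an additive shift exactly and keeps single batches", {
  withr::with_seed(12, {
    emb <- matrix(rnorm(60 * 4), 60, 4)
  })
  rownames(emb) <- paste0("c", 1:60)
  rs <- structure(list(embedding = emb, loadings = NULL, method = "pca",
                       sdev = NULL, depth_correlation = rep(NA_real_, 4),
                       retained_dims = 1:4), class = "reduced_space")
  shifted <- rs
  batch <- rep(c("a", "b"), each = 30)
  shifted$embedding[batch == "b", ] <-
    shifted$embedding[batch == "b", ] + 5
  fixed <- batch_center(shifted, batch)
  expect_equal(colMeans(fixed$embedding[batch == "a", ]),
               colMeans(fixed$embedding[batch == "b", ]), tolerance = 1e-12)
  same <- batch_center(rs, rep("a", 60))
  expect_equal(same$embedding, rs$embedding, tolerance = 1e-12)
})

test_that("gene activity matches a direct per-gene loop oracle", {
  co <- small_cohort()
  sub <- co$atac[1:40, ]
  genes <- co$genes[co$genes$chrom != "chrM", ][round(seq(1, 1800, length.out = 50)), ]
  act <- gene_activity(sub, genes, tile_intervals = co$tiles)
  # oracle: per tile, gap distance to every supplied gene's extended body;
  # the tile counts toward the nearest gene with weight exp(-d / 5000)
  tiles <- co$tiles
  ext_start <- pmax(ifelse(genes$strand == "+", genes$start - 2000, genes$start), 0)
  ext_end <- ifelse(genes$strand == "+", genes$end, genes$end + 2000)
  gap <- function(ts, te, gs, ge) {
    ifelse(te <= gs, gs - te, ifelse(ts >= ge, ts - ge, 0))
  }
  for (gi in sample(seq_len(nrow(genes)), 8)) {
    g <- genes[gi, ]
    cand <- which(tiles$chrom == g$chrom &
                    tiles$end > ext_start[gi] - 25000 &
                    tiles$start < ext_end[gi] + 25000)
    w <- numeric(length(cand))
    for (j in seq_along(cand)) {
      t <- tiles[cand[j], ]
      ds <- gap(t$start, t$end, ext_start, ext_end)
      ds[genes$chrom != t$chrom] <- Inf
      ok <- which(ds <= 25000)
      if (length(ok) == 0) next
      ws <- exp(-ds[ok] / 5000)
      best <- ok[which.max(ws)]
      if (genes$gene_id[best] == g$gene_id) w[j] <- max(ws)
    }
    want <- as.numeric(sub[, cand, drop = FALSE] %*% w)
    expect_equal(as.numeric(act[, g$gene_id]), want, tolerance = 1e-8)
  }
  # zero-accessibility gene scores zero
  empty <- sub; empty@x[] <- 0
  act0 <- gene_activity(empty, genes, tile_intervals = co$tiles)
  expect_equal(sum(act0), 0)
})

test_that("label transfer assigns exact matches with score 1 and excludes score 0.5", {
  withr::with_seed(13, {
    scaled <- matrix(rnorm(80 * 40), 80, 40,
                     dimnames = list(paste0("r", 1:80), paste0("g", 1:40)))
  })
  ref <- run_pca(scaled, n = 10, seed = 1)
  labels <- stats::setNames(rep(c("a", "b"), each = 40), rownames(scaled))
  ref_norm <- Matrix::Matrix(abs(scaled), sparse = TRUE)
  query <- Matrix::Matrix(exp(scaled[1:5, , drop = FALSE]), sparse = TRUE)
  rownames(query) <- paste0("q", 1:5)
  out <- label_transfer(ref, ref_norm, labels, query, k = 4, dims = 10)
  expect_true(all(out$labels$prediction_score >= 0.5))
  expect_true(all(out$labels$retained == (out$labels$prediction_score > 0.5)))
  expect_equal(dim(out$imputed), c(5, 40))

  # an exactly balanced neighborhood scores 0.5 and is excluded
  votes <- c("a", "a", "b", "b")
  tab <- sort(table(votes), decreasing = TRUE)
  expect_equal(as.numeric(tab[1]) / 4, 0.5)
})

test_that("cluster cell typing takes the majority and filters respect boundaries", {
  clusters <- tibble::tibble(cell = paste0("c", 1:10),
                             cluster = rep(1:2, each = 5))
  labels <- stats::setNames(c(rep("epi", 5), "epi", "epi", "epi", "mac", "mac"),
                            paste0("c", 1:10))
  types <- assign_cluster_celltypes(clusters, labels)
  expect_equal(types$label, c("epi", "epi"))
  expect_equal(types$purity, c(1, 0.6))

  rna <- stats::setNames(c(rep(6000, 5), rep(4999, 5)), paste0("c", 1:10))
  kept <- filter_clusters(types, clusters, rna_counts = rna,
                          rna_mean_min = 5000)
  expect_equal(kept$kept, c(TRUE, FALSE))
  rna2 <- stats::setNames(rep(5000, 10), paste0("c", 1:10))
  kept2 <- filter_clusters(types, clusters, rna_counts = rna2,
                           rna_mean_min = 5000)
  expect_true(all(kept2$kept))
})
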