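test_that("RNA QC applies strict-outlier boundary semantics", {
  counts <- matrix(0, 3, 4000)
  rownames(counts) <- c("removed_umi", "kept_boundary", "rich")
  colnames(counts) <- c(paste0("g", 1:3990), paste0("MT-", 1:10))
  # removed: umi 4999 (< 5000) although genes (3000) and mito (0) are fine
  counts["removed_umi", 1:2999] <- 1
  counts["removed_umi", 3000] <- 2000
  # kept: exactly umi 5000, genes 2000, mito 25.0
  counts["kept_boundary", 1:1999] <- 1
  counts["kept_boundary", 2000] <- 5000 - 1999 - 1250
  counts["kept_boundary", "MT-1"] <- 1250
  counts["rich", ] <- 3
  m <- Matrix::Matrix(counts, sparse = TRUE)
  res <- rna_qc_filter(m)
  qc <- res$qc
  expect_equal(qc$umi_count[qc$cell == "removed_umi"], 4999L)
  expect_equal(qc$umi_count[qc$cell == "kept_boundary"], 5000L)
  expect_equal(qc$pct_mito[qc$cell == "kept_boundary"], 25)
  expect_true(qc$keep[qc$cell == "kept_boundary"])
  expect_false(qc$keep[qc$cell == "removed_umi"])
  expect_error(rna_qc_filter(m, umi_min = 1e9), "no cells survive")
})

test_that("planted low-quality cells are exactly the ones removed from the cohort", {
  co <- small_cohort()
  res <- rna_qc_filter(co$rna, umi_min = 2000, genes_min = 500, mito_max = 25)
  truth <- co$truth$cell_table
  truth <- truth[truth$modality == "rna", ]
  removed <- res$qc$cell[!res$qc$keep]
  expect_setequal(removed, truth$barcode[truth$is_low_quality])
})

test_that("filtering is idempotent", {
  co <- small_cohort()
  first <- rna_qc_filter(co$rna, umi_min = 2000, genes_min = 500, mito_max = 25)
  second <- rna_qc_filter(first$counts, umi_min = 2000, genes_min = 500,
                          mito_max = 25)
  expect_equal(second$removed[["total"]], 0L)
  expect_equal(sum(first$qc$keep) + first$removed[["total"]], nrow(co$rna))
})

test_that("the mixture threshold lands between planted components", {
  withr::with_seed(21, {
    x <- c(rnorm(800, 2.5, 0.1), rnorm(1200, 4.0, 0.1))
  })
  cut <- gmm_depth_threshold(x)
  expect_gt(cut, 3.0)
  expect_lt(cut, 3.6)

  withr::with_seed(22, single <- rnorm(500, 3.2, 0.05))
  expect_equal(gmm_depth_threshold(single, floor = 3), 3)
  expect_error(gmm_depth_threshold(c(x, NA)), "non-finite")
  expect_error(gmm_depth_threshold(rnorm(10)), "at least 50")
})

test_that("TSS-proxy filtering keeps promoter-concentrated cells and drops flat ones", {
  co <- small_cohort()
  genes <- co$genes[co$genes$chrom != "chrM", ]
  tiles <- co$tiles
  n_tiles <- nrow(tiles)
  tss_tile_id <- paste0(genes$chrom, ":", (genes$tss %/% 500) * 500, "-",
                        (genes$tss %/% 500) * 500 + 500)
  tss_idx <- match(tss_tile_id, tiles$id)
  m <- Matrix::sparseMatrix(
    i = c(rep(1, length(tss_idx)), rep(2, n_tiles)),
    j = c(tss_idx, seq_len(n_tiles)),
    x = c(rep(5, length(tss_idx)), rep(1, n_tiles)),
    dims = c(3, n_tiles),
    dimnames = list(c("focused", "uniform", "empty"), tiles$id)
  )
  out <- tss_filter(m, co$genes)
  sc <- out$scores
  expect_true(sc$keep[sc$cell == "focused"])
  expect_false(sc$keep[sc$cell == "uniform"])
  # a uniform cell has score ~ 1, log10(2) ~ 0.301
  expect_equal(sc$log10_score[sc$cell == "uniform"], log10(2), tolerance = 0.01)
  expect_false(sc$keep[sc$cell == "empty"])
  expect_equal(sc$tss_score[sc$cell == "empty"], 0)
})

test_that("doublet scores separate planted cross-type doublets", {
  aucs <- vapply(1:3, function(s) {
    withr::with_seed(600 + s, {
      a <- matrix(rpois(150 * 300, 2), 150, 300)
      b <- matrix(rpois(150 * 300, 2), 150, 300)
      b[, 1:100] <- b[, 1:100] + rpois(150 * 100, 8)
      a[, 101:200] <- a[, 101:200] + rpois(150 * 100, 8)
      pairs <- cbind(sample(150, 16), sample(150, 16))
      doublets <- (a[pairs[, 1], ] + b[pairs[, 2], ])
    })
    m <- rbind(a, b, doublets)
    rownames(m) <- paste0("c", seq_len(nrow(m)))
    colnames(m) <- paste0("g", seq_len(ncol(m)))
    is_doublet <- c(rep(FALSE, 300), rep(TRUE, 16))
    sc <- doublet_scores(Matrix::Matrix(m, sparse = TRUE), k = 10,
                         modality = "rna", seed = s)
    r <- rank(sc$doublet_score)
    n_pos <- sum(is_doublet); n_neg <- sum(!is_doublet)
    (sum(r[is_doublet]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }, numeric(1))
  expect_true(all(aucs >= 0.9))
})

test_that("doublet removal caps at the expected count and zero ratio removes nothing", {
  sc <- tibble::tibble(cell = paste0("c", 1:1000),
                       doublet_score = seq(0, 1, length.out = 1000))
  kept <- doublet_filter(sc, filter_ratio = 0)
  expect_true(all(kept$keep))
  removed <- doublet_filter(sc, filter_ratio = 1, rate_per_1000 = 8)
  expect_equal(sum(!removed$keep), 8)  # 8 * (1000/1000)^2
  expect_true(all(removed$doublet_score[!removed$keep] >
                    min(removed$doublet_score[removed$keep])))
})
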