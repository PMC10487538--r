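toy_genome <- function(n_genes = 300) {
  gene_models(tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = "chr1",
    start = (seq_len(n_genes) - 1L) * 10000L,
    end = (seq_len(n_genes) - 1L) * 10000L + 2000L,
    strand = "+"
  ))
}

test_that("cells identical to the reference leave zero residuals", {
  genes <- toy_genome(200)
  withr::with_seed(31, {
    base <- matrix(rpois(60 * 200, 8), 60, 200,
                   dimnames = list(paste0("c", 1:60), genes$gene_id))
  })
  norm <- as.matrix(log_normalize(Matrix::Matrix(base, sparse = TRUE)))
  norm[31:60, ] <- norm[1:30, ]  # queries duplicate the reference
  rownames(norm) <- paste0("x", 1:60)
  prof <- infer_cnv(norm, genes, reference_cells = paste0("x", 1:30),
                    window = 21)
  expect_true(all(prof$residuals[paste0("x", 31:60), ] ==
                    prof$residuals[paste0("x", 1:30), ]))
  # toy scale: looser bound than the fixture-level invariant
  expect_lt(max(abs(rowMeans(prof$residuals[prof$reference_cells, ]))), 0.05)
})

test_that("moving averages preserve constants and validate the window", {
  m <- matrix(3, 50, 1)
  out <- peaklinks:::truncated_moving_average(m, 11)
  expect_true(all(abs(out - 3) < 1e-12))
  genes <- toy_genome(50)
  norm <- matrix(1, 25, 50, dimnames = list(paste0("c", 1:25), genes$gene_id))
  expect_error(infer_cnv(norm, genes, paste0("c", 1:5), window = 10), "odd")
  expect_warning(infer_cnv(norm, genes, paste0("c", 1:5), window = 101),
                 "fewer genes")
})

test_that("the profile is invariant to gene-order permutation of the input", {
  genes <- toy_genome(120)
  withr::with_seed(32, {
    counts <- matrix(rpois(40 * 120, 6), 40, 120,
                     dimnames = list(paste0("c", 1:40), genes$gene_id))
  })
  norm <- as.matrix(log_normalize(Matrix::Matrix(counts, sparse = TRUE)))
  prof1 <- infer_cnv(norm, genes, paste0("c", 1:10), window = 21)
  perm <- withr::with_seed(3, sample(120))
  prof2 <- infer_cnv(norm[, perm], genes, paste0("c", 1:10), window = 21)
  expect_equal(prof1$residuals, prof2$residuals[, colnames(prof1$residuals)])
})

test_that("a planted gain is visible in tumor cells and absent in the reference", {
  for (s in 1:3) {
    genes <- toy_genome(400)
    withr::with_seed(40 + s, {
      mu <- matrix(6, 120, 400)
      mu[61:120, 150:320] <- 9  # 1.5x gain spanning > 150 genome-ordered genes
      counts <- matrix(rpois(length(mu), mu), 120, 400,
                       dimnames = list(paste0("c", 1:120), genes$gene_id))
    })
    norm <- as.matrix(log_normalize(Matrix::Matrix(counts, sparse = TRUE)))
    prof <- infer_cnv(norm, genes, paste0("c", 1:60))
    seg <- genes$gene_id[175:300]
    seg <- intersect(seg, colnames(prof$residuals))
    tumor_mean <- mean(prof$residuals[paste0("c", 61:120), seg])
    ref_mean <- mean(prof$residuals[paste0("c", 1:60), seg])
    expect_gt(tumor_mean, 0.1)
    expect_lt(abs(ref_mean), 0.03)
  }
})

test_that("malignancy classification recovers planted tumor cells and spares the reference", {
  genes <- toy_genome(400)
  withr::with_seed(44, {
    mu <- matrix(6, 150, 400)
    mu[101:150, 120:300] <- 9
    counts <- matrix(rpois(length(mu), mu), 150, 400,
                     dimnames = list(paste0("c", 1:150), genes$gene_id))
  })
  norm <- as.matrix(log_normalize(Matrix::Matrix(counts, sparse = TRUE)))
  prof <- infer_cnv(norm, genes, paste0("c", 1:70))
  calls <- classify_malignant(prof)
  is_tumor <- calls$cells$cell %in% paste0("c", 101:150)
  called <- calls$cells$call == "tumor"
  expect_gt(sum(called & is_tumor) / sum(is_tumor), 0.9)
  expect_gt(sum(called & is_tumor) / sum(called), 0.9)
  # reference cells are never called tumor
  expect_false(any(calls$cells$call[calls$cells$cell %in%
                                      prof$reference_cells] == "tumor"))
  expect_error(classify_malignant(structure(list(residuals = norm[1:10, ],
                                                 scores = prof$scores[1:10, ],
                                                 reference_cells = "c1"),
                                            class = "cnv_profile")),
               "at least 20")
})

test_that("cluster-level calls require a clear majority", {
  genes <- toy_genome(400)
  withr::with_seed(45, {
    mu <- matrix(6, 120, 400)
    mu[81:120, 120:300] <- 9
    counts <- matrix(rpois(length(mu), mu), 120, 400,
                     dimnames = list(paste0("c", 1:120), genes$gene_id))
  })
  norm <- as.matrix(log_normalize(Matrix::Matrix(counts, sparse = TRUE)))
  prof <- infer_cnv(norm, genes, paste0("c", 1:60))
  clusters <- tibble::tibble(cell = paste0("c", 1:120),
                             cluster = rep(c(1L, 2L, 3L), each = 40))
  calls <- classify_malignant(prof, clusters = clusters)
  cl3 <- calls$clusters$call[calls$clusters$cluster == 3]
  expect_equal(cl3, "tumor")
  expect_true(all(calls$clusters$call[calls$clusters$cluster %in% 1:2] !=
                    "tumor"))
})
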