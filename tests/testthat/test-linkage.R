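test_that("iterative overlap merging keeps the best-scoring representative", {
  disjoint <- tibble::tibble(chrom = "chr1", start = c(0, 1000, 2000),
                             end = c(500, 1500, 2500), score = c(1, 2, 3))
  expect_equal(nrow(iterative_overlap_merge(disjoint)), 3)

  pair <- tibble::tibble(chrom = "chr1", start = c(0, 250),
                         end = c(500, 750), score = c(10, 5))
  kept <- iterative_overlap_merge(pair)
  expect_equal(kept$start, 0)

  # chain A-B-C where A overlaps B, B overlaps C, but A and C are disjoint:
  # hand-iterating keeps A (best) then C
  chain <- tibble::tibble(chrom = "chr1",
                          start = c(0, 400, 800), end = c(500, 900, 1300),
                          score = c(3, 2, 1))
  kept <- iterative_overlap_merge(chain)
  expect_equal(kept$start, c(0, 800))
})

test_that("peak annotation follows promoter > intronic > distal priority", {
  genes <- gene_models(tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1", start = c(10000L, 50000L),
    end = c(20000L, 60000L), strand = c("+", "-")
  ))
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(9000L, 15000L, 30000L, 60000L),
    end = c(9500L, 15500L, 30500L, 60500L),
    id = c("overTSS", "inBody", "far", "minusProm")
  )
  ann <- annotate_peaks(peaks, genes)
  cls <- stats::setNames(ann$peak_class, ann$id)
  expect_equal(cls[["overTSS"]], "promoter")   # upstream window of gp
  expect_equal(cls[["inBody"]], "intronic")
  expect_equal(cls[["far"]], "distal")
  expect_equal(cls[["minusProm"]], "promoter") # upstream of the minus gene
  exons <- tibble::tibble(chrom = "chr1", start = 14900L, end = 15600L,
                          id = "ex1")
  ann2 <- annotate_peaks(peaks, genes, exons = exons)
  expect_equal(ann2$peak_class[ann2$id == "inBody"], "exonic")
})

test_that("metacell groups have exactly k members and bounded pairwise overlap", {
  withr::with_seed(51, {
    emb <- matrix(rnorm(400 * 8), 400, 8)
  })
  rownames(emb) <- paste0("c", 1:400)
  mc <- make_metacells(emb, k = 40, n_groups = 15, seed = 1)
  expect_true(all(lengths(mc$groups) == 40))
  g <- length(mc$groups)
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      expect_lte(length(intersect(mc$groups[[i]], mc$groups[[j]])),
                 mc$max_shared)
    }
  }
  singles <- make_metacells(emb, k = 1, max_shared = 0, n_groups = 30, seed = 1)
  expect_true(all(lengths(singles$groups) == 1))
  expect_equal(anyDuplicated(unlist(singles$groups)), 0)
  expect_error(make_metacells(emb, k = 500), "exceeds")
})

test_that("metacell aggregation sums members and supports all normalizations", {
  withr::with_seed(52, {
    m <- Matrix::Matrix(matrix(rpois(60 * 10, 4), 60, 10,
                               dimnames = list(paste0("c", 1:60),
                                               paste0("f", 1:10))),
                        sparse = TRUE)
  })
  grouping <- structure(list(groups = list(1:10, 11:30), cells = rownames(m),
                             k = 10, max_shared = 5),
                        class = "metacell_grouping")
  sums <- aggregate_metacells(m, grouping, "sum")
  expect_equal(as.numeric(sums[1, ]), unname(Matrix::colSums(m[1:10, ])))
  means <- aggregate_metacells(m, grouping, "mean")
  expect_equal(as.numeric(means[2, ]), unname(Matrix::colSums(m[11:30, ]) / 20))
  logn <- aggregate_metacells(m, grouping, "lognorm")
  expect_equal(as.matrix(logn), as.matrix(log_normalize(sums)))
  dense <- aggregate_metacells(as.matrix(m), grouping, "sum")
  expect_equal(as.matrix(dense), as.matrix(sums))
})

test_that("peak-gene correlations match the direct formula oracle", {
  withr::with_seed(53, {
    n <- 50
    atac_mc <- matrix(rnorm(n * 10), n, 10)
    rna_mc <- matrix(rnorm(n * 10), n, 10)
    rna_mc[, 1] <- atac_mc[, 1]  # an exact duplicate pair
  })
  starts <- (0:9) * 20000L + 100000L
  peaks <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 500L)
  peaks <- genomic_intervals(peaks)
  colnames(atac_mc) <- peaks$id
  genes <- gene_models(tibble::tibble(
    gene_id = paste0("g", 1:10), chrom = "chr1",
    start = starts + 5000L, end = starts + 7000L, strand = "+"
  ))
  colnames(rna_mc) <- genes$gene_id
  rownames(atac_mc) <- rownames(rna_mc) <- paste0("m", 1:n)
  links <- correlate_peak_gene(atac_mc, rna_mc, peaks, genes)
  self <- links[links$peak_id == peaks$id[1] & links$gene_id == "g1", ]
  expect_equal(self$r, 1, tolerance = 1e-12)

  for (i in seq_len(min(100, nrow(links)))) {
    x <- atac_mc[, links$peak_id[i]]
    y <- rna_mc[, links$gene_id[i]]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(links$r[i], r, tolerance = 1e-10)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(links$p[i], 2 * stats::pt(-abs(tt), n - 2), tolerance = 1e-10)
  }
  expect_equal(links$fdr, benjamini_hochberg(links$p), tolerance = 1e-12)

  # zero-variance features are skipped and counted
  atac0 <- atac_mc; atac0[, 2] <- 1
  links0 <- correlate_peak_gene(atac0, rna_mc, peaks, genes)
  expect_gt(attr(links0, "n_skipped"), 0)
  expect_false(peaks$id[2] %in% links0$peak_id)
})

test_that("the BH monotonicity invariant holds on candidate tables", {
  withr::with_seed(54, {
    p <- runif(500)^2
  })
  q <- benjamini_hochberg(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q >= p * 1 / length(p) * rank(p) / rank(p) - 1e-12))
  expect_true(all(q[ord] >= (p[ord] * length(p) / seq_along(p)) - 1e-9 |
                    q[ord] <= 1))
})

test_that("link filtering applies inclusive thresholds and the distal class", {
  links <- tibble::tibble(
    peak_id = c("a", "b", "c", "d"),
    gene_id = "g",
    r = c(0.45, 0.44, 0.9, 0.9),
    p = 1e-20, fdr = c(1e-13, 1e-13, 1e-13, 2e-12),
    distance_bp = 1000L,
    peak_class = c("distal", "distal", "promoter", "distal")
  )
  kept <- filter_links(links)
  expect_equal(kept$peak_id, "a")  # r = 0.45 exactly is kept
  expect_equal(nrow(filter_links(links[0, ])), 0)
  expect_equal(attr(kept, "summary")$n_unique_peaks, 1)
})

test_that("k-means link clustering recovers constructed cell-type blocks", {
  types <- paste0("t", 1:5)
  n_per <- 30
  link_type <- rep(1:5, each = n_per)
  peak_profiles <- matrix(0.2, 5, 150,
                          dimnames = list(types, paste0("p", 1:150)))
  gene_profiles <- matrix(0.2, 5, 150,
                          dimnames = list(types, paste0("g", 1:150)))
  for (i in seq_along(link_type)) {
    peak_profiles[link_type[i], i] <- 5
    gene_profiles[link_type[i], i] <- 5
  }
  links <- tibble::tibble(peak_id = paste0("p", 1:150),
                          gene_id = paste0("g", 1:150),
                          r = 0.8, p = 0, fdr = 0, distance_bp = 0L,
                          peak_class = "distal")
  out <- kmeans_links(links, peak_profiles, gene_profiles, k = 5, seed = 1)
  tab <- table(out$kmeans_cluster, link_type)
  expect_equal(sum(apply(tab, 1, max)), 150)  # perfect 5-way recovery
  labs <- attr(out, "cluster_labels")
  expect_setequal(labs$celltype, types)

  one <- kmeans_links(links, peak_profiles, gene_profiles, k = 1, seed = 1)
  expect_equal(unique(one$kmeans_cluster), 1L)

  # row scaling makes the clustering invariant to per-link affine rescaling
  scaled_peaks <- peak_profiles * 7 + 3
  out2 <- kmeans_links(links, scaled_peaks, gene_profiles, k = 5, seed = 1)
  tab2 <- table(out$kmeans_cluster, out2$kmeans_cluster)
  expect_equal(sum(apply(tab2, 1, max)), 150)
})
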