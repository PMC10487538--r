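toy_call_inputs <- function() {
  peaks <- genomic_intervals(tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 3000L, 5000L, 7000L),
    end = c(1500L, 3500L, 5500L, 7500L),
    id = c("p1", "p2", "p3", "p4")
  ))
  links <- tibble::tibble(
    peak_id = c("p1", "p1", "p2", "p3", "p4"),
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    r = 0.8, p = 0, fdr = 0, distance_bp = 10000L, peak_class = "distal",
    kmeans_cluster = c(1L, 1L, 1L, 2L, 1L)
  )
  list(peaks = peaks, links = links)
}

test_that("cancer-specific calling excludes 1-bp overlaps but keeps half-open adjacency", {
  inp <- toy_call_inputs()
  reference <- genomic_intervals(tibble::tibble(
    chrom = "chr1",
    start = c(1499L, 3500L),  # 1 bp into p1; exactly adjacent to p2
    end = c(2000L, 4000L)
  ))
  cs <- call_cancer_specific(inp$links, tumor_clusters = 1L, inp$peaks,
                             reference)
  expect_setequal(cs$reference_overlapping$id, "p1")
  expect_setequal(cs$cancer_specific$id, c("p2", "p4"))
  # partition identities
  expect_length(intersect(cs$cancer_specific$id, cs$reference_overlapping$id), 0)
  expect_setequal(c(cs$cancer_specific$id, cs$reference_overlapping$id),
                  cs$cancer_enriched$id)
  empty_ref <- inp$peaks[0, ]
  expect_warning(
    all_spec <- call_cancer_specific(inp$links, 1L, inp$peaks, empty_ref),
    "empty"
  )
  expect_equal(nrow(all_spec$reference_overlapping), 0)
})

test_that("the subtraction equals a brute-force oracle on random sets", {
  peaks <- genomic_intervals(random_intervals(120, seed = 61))
  reference <- genomic_intervals(random_intervals(80, seed = 62))
  links <- tibble::tibble(peak_id = peaks$id, gene_id = "g", r = 0.9, p = 0,
                          fdr = 0, distance_bp = 0L, peak_class = "distal",
                          kmeans_cluster = 1L)
  cs <- call_cancer_specific(links, 1L, peaks, reference)
  overlapping <- unique(overlap_oracle(peaks, reference)$id_a)
  expect_setequal(cs$reference_overlapping$id, overlapping)
  expect_setequal(cs$cancer_specific$id, setdiff(peaks$id, overlapping))
})

test_that("regulatory load reports per-set means and the rank-sum contrast", {
  inp <- toy_call_inputs()
  reference <- inp$peaks[0, ]
  suppressWarnings(cs <- call_cancer_specific(inp$links, 1L, inp$peaks,
                                              reference))
  # cancer set: p1 (2 genes), p2 (1), p4 (1); comparison: p3 (1)
  load <- regulatory_load(cs, inp$links, comparison_peak_ids = "p3")
  s <- load$summary
  expect_equal(s$mean_genes_per_peak[s$set == "cancer_specific"], 4 / 3)
  expect_equal(s$mean_genes_per_peak[s$set == "comparison"], 1)
  expect_equal(s$total_linked_genes, c(4L, 1L))

  # {2,2,1} vs {1,1,1} arithmetic
  links2 <- tibble::tibble(
    peak_id = c("a", "a", "b", "b", "c", "x", "y", "z"),
    gene_id = paste0("g", 1:8)
  )
  cs2 <- structure(list(cancer_specific = tibble::tibble(id = c("a", "b", "c"))),
                   class = "enhancer_call_set")
  load2 <- regulatory_load(cs2, links2, c("x", "y", "z"))
  expect_equal(load2$summary$mean_genes_per_peak, c(5 / 3, 1))
  # identical distributions give p = 1
  load3 <- regulatory_load(cs2, links2, c("a", "b", "c"))
  expect_equal(load3$p_value, 1)
})

test_that("upregulated linked genes honour strict DE cutoffs and linkage", {
  inp <- toy_call_inputs()
  suppressWarnings(cs <- call_cancer_specific(inp$links, 1L, inp$peaks,
                                              inp$peaks[0, ]))
  de <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g9"),
    log2fc = c(1.01, 0.99, 2, 3),
    padj = c(0.005, 0.001, 0.02, 1e-6)
  )
  sel <- select_upregulated_linked_genes(de, cs, inp$links)
  expect_equal(sel$gene_id, "g1")   # g2 fails log2fc, g3 fails padj,
                                    # g9 is significant but unlinked
  expect_equal(sel$n_enhancers, 1L)
})

test_that("super-enhancer candidates need many clustered, co-correlated links", {
  starts <- c(0L, 2000L, 4000L, 6000L, 8000L, 10000L, 500000L)
  peaks <- genomic_intervals(tibble::tibble(
    chrom = "chr1", start = starts, end = starts + 500L,
    id = paste0("p", 1:7)
  ))
  withr::with_seed(63, {
    shared <- rnorm(40)
    amc <- vapply(1:7, function(i) shared + rnorm(40, sd = 0.2), numeric(40))
  })
  colnames(amc) <- peaks$id
  rownames(amc) <- paste0("m", 1:40)
  links6 <- tibble::tibble(peak_id = paste0("p", 1:6), gene_id = "hub")
  expect_equal(superenhancer_candidates(links6, amc, peaks)$gene_id, "hub")
  # only one link: not flagged
  expect_equal(nrow(superenhancer_candidates(links6[1, ], amc, peaks)), 0)
  # six links but spanning 500 kb: span violated
  links_spread <- tibble::tibble(peak_id = paste0("p", c(1:5, 7)),
                                 gene_id = "hub")
  expect_equal(nrow(superenhancer_candidates(links_spread, amc, peaks)), 0)
  # six clustered links without mutual correlation: not flagged
  withr::with_seed(64, {
    amc_uncor <- matrix(rnorm(40 * 7), 40, 7,
                        dimnames = dimnames(amc))
  })
  expect_equal(nrow(superenhancer_candidates(links6, amc_uncor, peaks)), 0)
})
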