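#' Run the full enhancer-annotation pipeline on a matched cohort
#'
#' Orchestrates the study workflow end to end on a `synthetic_cohort` (or any
#' object with the same fields): RNA QC and doublet removal; normalization,
#' variable-gene selection, scaling with mitochondrial regression, PCA,
#' per-sample centering and graph clustering; marker-based cell typing; CNV
#' inference and malignancy calls on the male patients; ATAC QC
#' (mixture-model depth threshold, TSS-proxy filter, simulated-doublet
#' removal); iterative LSI; cross-modality label transfer with imputed
#' expression; metacell construction; peak-to-gene correlation, filtering
#' and k-means clustering of links; cancer-specific enhancer calling,
#' regulatory load and DE-linked gene selection.
#'
#' Thresholds default to the desk-scale fixture: QC cutoffs are scaled to
#' the synthetic depth distributions while all statistical thresholds (link
#' r >= 0.45 and FDR <= 1e-12, distal class, label score > 0.5, DE filters,
#' LSI settings) are the analysis defaults.
#'
#' @param cohort A `synthetic_cohort` (see [generate_cohort()]).
#' @param seed Seed driving every stochastic stage.
#' @param umi_min,genes_min,mito_max RNA QC cutoffs (fixture-scaled
#'   defaults 2000, 500, 25).
#' @param n_hvg,pca_dims,cluster_resolution RNA reduction settings
#'   (defaults 2000, 30, 0.8).
#' @param lsi_n_var,lsi_dims,lsi_cor_cutoff ATAC LSI settings (defaults
#'   25000, 30, 0.75).
#' @param transfer_k,min_prediction_score Label-transfer settings (defaults
#'   15, 0.5).
#' @param impute_k Imputation neighborhood (default 15).
#' @param metacell_k Cells per metacell (default 100).
#' @param metacell_groups Number of low-overlap metacell aggregates drawn
#'   (default NULL: one group per 20 cells, capped at 500).
#' @param link_r_min,link_fdr_max Link filter (defaults 0.45, 1e-12).
#' @param max_dist Candidate window in bp (default 250000).
#' @param kmeans_k Link clusters (default 5).
#' @return A list of stage results (see elements `qc`, `rna`, `clusters`,
#'   `cnv`, `atac`, `transfer`, `links`, `enhancers`, `de`).
#' @export
run_pipeline <- function(cohort, seed = 1L,
                         umi_min = 2000, genes_min = 500, mito_max = 25,
                         n_hvg = 2000, pca_dims = 30, cluster_resolution = 0.8,
                         lsi_n_var = 25000, lsi_dims = 30, lsi_cor_cutoff = 0.75,
                         transfer_k = 15, impute_k = 15,
                         min_prediction_score = 0.5,
                         metacell_k = 100, metacell_groups = NULL,
                         link_r_min = 0.45,
                         link_fdr_max = 1e-12, max_dist = 250000,
                         kmeans_k = 5) {
  seed <- as.integer(seed)
  cells <- cohort$truth$cell_table
  sample_of <- stats::setNames(cells$sample, cells$barcode)
  sex_of <- stats::setNames(cells$sex, cells$barcode)

  ## ---- RNA: QC, doublets, reduction, clustering, typing ----
  rna_qc <- rna_qc_filter(cohort$rna, umi_min = umi_min, genes_min = genes_min,
                          mito_max = mito_max)
  rna_counts <- rna_qc$counts
  dbl <- doublet_scores(rna_counts, k = 10, modality = "rna", seed = seed + 1L)
  rate_per_1000 <- 1000 * 1000 * cohort$config$doublet_rate / nrow(rna_counts)
  dbl <- doublet_filter(dbl, filter_ratio = 1.0, rate_per_1000 = rate_per_1000)
  rna_counts <- rna_counts[dbl$cell[dbl$keep], , drop = FALSE]
  rna_norm <- log_normalize(rna_counts)
  hvg <- select_hvg(rna_counts, n_top = min(n_hvg, ncol(rna_counts)))
  pct_mito <- rna_qc$qc$pct_mito[match(rownames(rna_counts), rna_qc$qc$cell)]
  scaled <- scale_and_regress(rna_norm[, hvg, drop = FALSE], covariate = pct_mito)
  pca <- run_pca(scaled, n = 50, seed = seed + 2L)
  pca <- batch_center(pca, sample_of[rownames(scaled)])
  clusters <- cluster_graph(pca, k_nn = 20, resolution = cluster_resolution,
                            dims = pca_dims, seed = seed + 3L)
  mk <- marker_scores(rna_norm, cohort$marker_sets)
  cell_labels <- stats::setNames(mk$label, mk$cell)
  cluster_types <- assign_cluster_celltypes(clusters, cell_labels)
  cluster_of <- stats::setNames(clusters$cluster, clusters$cell)
  label_of <- stats::setNames(
    cluster_types$label[match(clusters$cluster, cluster_types$cluster)],
    clusters$cell
  )
  kept_info <- filter_clusters(
    cluster_types, clusters,
    rna_counts = stats::setNames(
      Matrix::rowSums(rna_counts), rownames(rna_counts)),
    rna_mean_min = umi_min
  )

  ## ---- CNV, separately within each male patient sample ----
  cnv <- list()
  cnv_cell_rows <- list()
  for (smp in c("P1", "P2")) {
    smp_cells <- rownames(rna_norm)[sample_of[rownames(rna_norm)] == smp]
    ref_cells <- smp_cells[label_of[smp_cells] %in% c("macrophage", "endothelial")]
    profile <- infer_cnv(rna_norm[smp_cells, , drop = FALSE], cohort$genes,
                         ref_cells)
    calls <- classify_malignant(
      profile, clusters = clusters[clusters$cell %in% smp_cells, , drop = FALSE]
    )
    cnv[[smp]] <- list(profile = profile, calls = calls)
    cnv_cell_rows[[smp]] <- calls$cells
  }
  cnv_calls <- list(
    cells = dplyr::bind_rows(cnv_cell_rows),
    clusters = dplyr::bind_rows(
      lapply(names(cnv), function(smp) {
        dplyr::mutate(cnv[[smp]]$calls$clusters, sample = smp, .before = 1)
      })
    )
  )

  ## ---- ATAC: QC, LSI, transfer ----
  atac <- cohort$atac
  frag <- Matrix::rowSums(atac)
  keep_depth <- rep(FALSE, nrow(atac))
  gmm_cuts <- list()
  for (smp in unique(sample_of[rownames(atac)])) {
    idx <- which(sample_of[rownames(atac)] == smp)
    cut <- gmm_depth_threshold(log10(frag[idx] + 1), seed = seed + 4L)
    gmm_cuts[[smp]] <- cut
    keep_depth[idx] <- log10(frag[idx] + 1) >= cut
  }
  atac <- atac[keep_depth, , drop = FALSE]
  tssf <- tss_filter(atac, cohort$genes)
  atac <- tssf$counts
  adbl <- doublet_scores(atac, k = 10, modality = "atac", seed = seed + 5L)
  arate <- 1000 * 1000 * cohort$config$doublet_rate / nrow(atac)
  adbl <- doublet_filter(adbl, filter_ratio = 1.0, rate_per_1000 = arate)
  atac <- atac[adbl$cell[adbl$keep], , drop = FALSE]
  lsi <- iterative_lsi(atac, n_var = lsi_n_var, dims = lsi_dims,
                       cor_cutoff = lsi_cor_cutoff, seed = seed + 6L)
  lsi <- batch_center(lsi, sample_of[rownames(atac)])
  activity <- gene_activity(atac, cohort$genes,
                            tile_intervals = cohort$tiles[
                              match(colnames(atac), cohort$tiles$id), ])
  transfer <- label_transfer(
    pca, rna_norm, label_of, activity, k = transfer_k, impute_k = impute_k,
    min_score = min_prediction_score, dims = pca_dims,
    ref_samples = sample_of[rownames(pca$embedding)],
    query_samples = sample_of[rownames(atac)],
    constrain_by_sample = TRUE
  )
  retained <- transfer$labels$cell[transfer$labels$retained]
  atac_labels <- stats::setNames(transfer$labels$label, transfer$labels$cell)

  ## ---- metacells and peak-to-gene links ----
  lsi_kept <- lsi
  keep_idx <- match(retained, rownames(lsi$embedding))
  lsi_kept$embedding <- lsi$embedding[keep_idx, , drop = FALSE]
  metacells <- make_metacells(lsi_kept, k = min(metacell_k, length(retained)),
                              n_groups = metacell_groups, seed = seed + 7L)
  peak_counts <- atac[retained, cohort$peaks$id, drop = FALSE]
  atac_mc <- aggregate_metacells(peak_counts, metacells, normalize = "lognorm")
  rna_mc <- aggregate_metacells(transfer$imputed[retained, , drop = FALSE],
                                metacells, normalize = "mean")
  candidate_links <- correlate_peak_gene(atac_mc, rna_mc, cohort$peaks,
                                         cohort$genes, max_dist = max_dist)
  links <- filter_links(candidate_links, r_min = link_r_min,
                        fdr_max = link_fdr_max)
  peak_norm <- log_normalize(peak_counts)
  peak_profiles <- celltype_means(peak_norm, atac_labels[retained])
  gene_profiles <- celltype_means(transfer$imputed[retained, , drop = FALSE],
                                  atac_labels[retained])
  links <- kmeans_links(links, peak_profiles, gene_profiles,
                        k = kmeans_k, seed = seed + 8L)
  cluster_celltypes <- attr(links, "cluster_labels")

  ## ---- enhancers, regulatory load, DE ----
  tumor_clusters <- cluster_celltypes$kmeans_cluster[
    cluster_celltypes$celltype == "epi_tumor"]
  call_set <- call_cancer_specific(links, tumor_clusters, cohort$peaks,
                                   cohort$reference_enhancers)
  lineage_peak_ids <- setdiff(unique(links$peak_id),
                              unique(links$peak_id[links$kmeans_cluster %in%
                                                     tumor_clusters]))
  load <- regulatory_load(call_set, links, lineage_peak_ids)
  male_tumor <- names(label_of)[label_of == "epi_tumor" &
                                  sex_of[names(label_of)] == "male"]
  female_tumor <- names(label_of)[label_of == "epi_tumor" &
                                    sex_of[names(label_of)] == "female"]
  de <- wilcoxon_de(rna_norm, male_tumor, female_tumor, seed = seed + 9L,
                    return_all = TRUE)
  de_sig <- de[de$padj < 0.01, , drop = FALSE]
  up_linked <- select_upregulated_linked_genes(de_sig, call_set, links)
  supers <- superenhancer_candidates(links, atac_mc, cohort$peaks)

  list(
    qc = list(rna = rna_qc$qc, rna_doublets = dbl, atac_gmm_cuts = gmm_cuts,
              atac_tss = tssf$scores, atac_doublets = adbl),
    rna = list(normalized = rna_norm, hvg = hvg, pca = pca),
    clusters = list(assignment = clusters, types = cluster_types,
                    cell_labels = label_of, filter = kept_info),
    cnv = list(per_patient = cnv, calls = cnv_calls),
    atac = list(counts = atac, lsi = lsi, activity = activity),
    transfer = transfer,
    metacells = metacells,
    links = list(candidates = candidate_links, filtered = links,
                 cluster_celltypes = cluster_celltypes,
                 atac_mc = atac_mc, rna_mc = rna_mc),
    enhancers = list(call_set = call_set, regulatory_load = load,
                     upregulated_linked = up_linked,
                     superenhancers = supers),
    de = de,
    seed = seed
  )
}

#' Write the pipeline's tabular outputs to TSV
#'
#' The files written are the determinism surface of the pipeline: links,
#' link-cluster labels, cancer-specific enhancer BED, regulatory load,
#' DE table, CNV calls and per-cell labels.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (is.null(x)) x <- tibble::tibble(empty = logical())
    readr::write_tsv(x, file.path(dir, name), progress = FALSE)
    file.path(dir, name)
  }
  paths <- c(
    w(result$links$filtered, "links.tsv"),
    w(result$links$cluster_celltypes, "link_clusters.tsv"),
    w(result$enhancers$regulatory_load$summary, "regulatory_load.tsv"),
    w(result$enhancers$upregulated_linked, "upregulated_linked_genes.tsv"),
    w(result$de, "de.tsv"),
    w(result$cnv$calls$cells, "cnv_calls.tsv"),
    w(tibble::tibble(cell = names(result$clusters$cell_labels),
                     label = unname(result$clusters$cell_labels)),
      "cell_labels.tsv")
  )
  write_bed(result$enhancers$call_set$cancer_specific,
            file.path(dir, "cancer_specific.bed"))
  invisible(c(paths, file.path(dir, "cancer_specific.bed")))
}

#' Compare recovered links with the planted truth
#'
#' @param links A filtered link tibble (`peak_id`, `gene_id`).
#' @param truth_links The cohort's `truth$planted_links`.
#' @return A one-row tibble: `n_predicted`, `n_true`, `n_correct`, `recall`,
#'   `precision`.
#' @export
evaluate_links <- function(links, truth_links) {
  pred <- unique(paste(links$peak_id, links$gene_id))
  true <- unique(paste(truth_links$peak_id, truth_links$gene_id))
  n_correct <- length(intersect(pred, true))
  tibble::tibble(
    n_predicted = length(pred), n_true = length(true), n_correct = n_correct,
    recall = if (length(true)) n_correct / length(true) else NA_real_,
    precision = if (length(pred)) n_correct / length(pred) else NA_real_
  )
}

#' Compare per-cell malignancy calls with the planted truth
#'
#' @param calls Per-cell tibble from [classify_malignant()] (`cell`, `call`).
#' @param cell_table The cohort's `truth$cell_table`.
#' @param tumor_samples Samples whose epithelial cells carry planted CNVs
#'   (default P1 and P2).
#' @return A one-row tibble with tumor `recall` and `precision`.
#' @export
evaluate_cnv_calls <- function(calls, cell_table, tumor_samples = c("P1", "P2")) {
  truth <- cell_table[match(calls$cell, cell_table$barcode), ]
  is_true_tumor <- truth$cell_type == "epi_tumor" &
    truth$sample %in% tumor_samples & !truth$is_doublet & !truth$is_low_quality
  eval_cells <- !truth$is_doublet & !truth$is_low_quality
  pred <- calls$call == "tumor" & eval_cells
  tp <- sum(pred & is_true_tumor)
  tibble::tibble(
    n_true = sum(is_true_tumor & eval_cells),
    n_called = sum(pred),
    recall = tp / sum(is_true_tumor & eval_cells),
    precision = if (sum(pred)) tp / sum(pred) else NA_real_
  )
}

#' Null link count under metacell permutation
#'
#' Breaks the peak-gene coupling by permuting the metacell rows of the RNA
#' side and recounts links passing the filter, leaving everything else
#' (candidate pairs, thresholds, FDR machinery) identical.
#'
#' @param atac_mc,rna_mc Metacell matrices from the pipeline.
#' @param peaks,genes As in [correlate_peak_gene()].
#' @param seed Permutation seed.
#' @param ... Passed to [correlate_peak_gene()] / [filter_links()].
#' @param r_min,fdr_max Filter thresholds (defaults 0.45, 1e-12).
#' @return Number of passing links after permutation.
#' @export
permuted_link_count <- function(atac_mc, rna_mc, peaks, genes, seed = 1L,
                                r_min = 0.45, fdr_max = 1e-12, ...) {
  withr::local_seed(seed)
  perm <- sample(nrow(rna_mc))
  shuffled <- rna_mc[perm, , drop = FALSE]
  rownames(shuffled) <- rownames(rna_mc)
  cand <- correlate_peak_gene(atac_mc, shuffled, peaks, genes, ...)
  nrow(filter_links(cand, r_min = r_min, fdr_max = fdr_max))
}
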