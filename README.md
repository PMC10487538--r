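# peaklinks

Matched single-cell RNA-seq and single-cell ATAC-seq of a tumor make it
possible to ask which distal open-chromatin peaks behave like enhancers of
which genes, and which of those enhancers are specific to the malignant
cells rather than to the normal lineage. `peaklinks` is a tested, reusable
R implementation of that analysis: from raw CellRanger-style count matrices
to malignant-cell calling, peak-to-gene linkage, cancer-specific enhancer
identification, regulatory-load statistics, case-versus-comparator
differential expression, and transcription-factor motif analysis. A
synthetic matched-multiome generator with planted ground truth ships with
the package, so every stage of the pipeline is testable end to end without
any controlled-access download.

## The analysis in brief

* **QC and doublets.** RNA cells are outliers if UMI < 5,000, genes
  expressed < 2,000 or percent-mitochondrial > 25 (strict inequalities;
  boundary cells are kept). ATAC cells pass a per-sample depth threshold
  estimated by a two-component Gaussian mixture on log10 fragments and a
  TSS-enrichment proxy cut at log10(score + 1) ≥ 0.9. Doublets are scored
  by the fraction of simulated (averaged-pair) doublets among each cell's
  nearest neighbors and removed at filterRatio × the expected rate.
* **Reduction.** RNA: log-normalize, 2,000 variable genes ("vst"-style
  standardized variance), scaling with mitochondrial regression, PCA, 30
  components, per-sample centering, shared-nearest-neighbor Louvain at
  resolution 0.8. ATAC: 500-bp tile matrix, two rounds of TF-IDF + truncated
  SVD on the 25,000 most variable tiles (iterative LSI), dimensions with
  |cor(dim, log10 depth)| > 0.75 dropped.
* **Malignancy.** Within each patient, expression relative to an
  immune/endothelial reference is smoothed over 101 genome-ordered genes
  (expression cutoff 0.1, denoising at 1.5 reference SDs); each cell gets a
  CNV score (mean squared residual) and a correlation with the mean profile
  of the top-5% cells, and cells/clusters are called tumor, normal or
  unassigned from that scatter.
* **Linkage.** ATAC cell-type labels and an imputed transcriptome come from
  projection + k-nearest-neighbor label transfer (prediction score ≤ 0.5
  excluded). Low-overlap metacells (~100 cells each) are built by kNN in
  LSI space; for every peak-gene pair within 250 kb the Pearson correlation
  of aggregated accessibility and imputed expression is tested
  (t-statistic), BH-corrected, and kept when r ≥ 0.45, FDR ≤ 1e-12 and the
  peak is distal. Filtered links are k-means clustered (k = 5) on their
  per-cell-type profiles.
* **Cancer-specific enhancers.** Peaks from tumor-enriched link clusters
  that share not even 1 bp with a reference normal-epithelium enhancer set
  are cancer-specific. Their per-peak linked-gene counts (regulatory load)
  are compared with the non-epithelial distal peaks by a two-sided Wilcoxon
  rank-sum test, and genes upregulated in the case cohort (log2FC > 1,
  adjusted p < 0.01, Wilcoxon marker test with the conventional detection
  filters) that link to a cancer-specific enhancer are reported, along with
  super-enhancer candidates (> 5 mutually correlated, genomically clustered
  links to one promoter).
* **Motifs.** MEME-format PWMs are scanned FIMO-style: log2-odds scores,
  exact p-values from a dynamic program over the discretized null score
  distribution, BH q-values over all windows, q < 0.01 reported, ranked by
  the malignant-cell expression of the corresponding factor; containment
  enrichment between peak sets uses the hypergeometric test at
  FDR < 0.01 and log2FC > 1.

## Worked example

```r
library(peaklinks)

cohort <- generate_cohort(cohort_config(seed = 42))
cohort
#> <synthetic_cohort> 3000 RNA cells x 2010 genes; 3000 ATAC cells x 40000 tiles;
#>   6000 peaks; 134 planted links

result <- run_pipeline(cohort, seed = 42)

links <- result$links$filtered
dplyr::select(head(links, 4), peak_id, gene_id, r, fdr, distance_bp, kmeans_cluster)
#>   peak_id              gene_id     r      fdr distance_bp kmeans_cluster
#> 1 chr1:1057500-1058000 G0082   0.809 5.64e-21      -40251              3
#> 2 chr1:1157500-1158000 G0090   0.765 3.48e-17      -40251              5
#> 3 chr1:1257500-1258000 G0098   0.842 1.82e-24      -40251              1
#> 4 chr1:1257500-1258000 G0103   0.823 2.34e-22      -20250              1

evaluate_links(links, cohort$truth$planted_links)
#>   n_predicted n_true n_correct recall precision
#> 1         139    134       134      1     0.964
```

All 134 planted enhancer-gene links are recovered and 96% of reported
links are planted ones. The cancer-specific enhancers carry roughly twice
the regulatory load of the lineage peaks, reproducing the directional
contrast the method is built to detect:

```r
result$enhancers$regulatory_load$summary
#>   set             n_peaks mean_genes_per_peak total_linked_genes
#> 1 cancer_specific      34                2.06                 70
#> 2 comparison           65                1.03                 67
#> rank-sum p = 3.97e-21

evaluate_cnv_calls(result$cnv$calls$cells, cohort$truth$cell_table)
#>   n_true n_called recall precision
#> 1    505      498  0.968     0.982
```

`mean_genes_per_peak` is the average number of genes linked to each peak;
the per-cell malignancy calls recover 97% of the planted tumor cells at
98% precision. Result tables are tibbles, fitted objects have `tidy()` /
`glance()` methods, and `autoplot()` / `plot_*()` helpers draw the standard
diagnostics (embeddings, CNV scatter, link volcano, regulatory load).

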