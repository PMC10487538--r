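#' Cancer-specific enhancer calling by interval subtraction
#'
#' Takes the distal peaks participating in tumor-enriched link clusters and
#' splits them by overlap against a reference enhancer set (e.g. normal
#' mammary epithelium H3K27ac peaks): any overlap of `min_overlap` bp or more
#' makes a peak reference-overlapping; the remainder — sharing not even one
#' base with the reference — are the cancer-specific enhancers. Half-open
#' adjacency (a peak ending where a reference enhancer starts) does not
#' count as overlap.
#'
#' @param links Filtered link tibble with a `kmeans_cluster` column.
#' @param tumor_clusters Integer ids of the tumor-enriched k-means clusters.
#' @param peaks Interval tibble covering the link peaks.
#' @param reference_enhancers Interval tibble of reference enhancers; an
#'   empty set makes every peak cancer-specific, with a loud warning.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return An `enhancer_call_set`: list with `cancer_enriched` (interval
#'   tibble of all tumor-cluster peaks), `cancer_specific`,
#'   `reference_overlapping` (its complement), and `linked_gene_count`
#'   (tibble: `peak_id`, `n_genes`).
#' @export
call_cancer_specific <- function(links, tumor_clusters, peaks,
                                 reference_enhancers, min_overlap = 1L) {
  stopifnot("kmeans_cluster" %in% names(links))
  tumor_links <- links[links$kmeans_cluster %in% tumor_clusters, , drop = FALSE]
  peaks <- genomic_intervals(peaks)
  enriched <- peaks[peaks$id %in% unique(tumor_links$peak_id), , drop = FALSE]
  if (nrow(reference_enhancers) == 0) {
    warning("reference enhancer set is empty: every cancer-enriched peak ",
            "will be called cancer-specific", call. = FALSE)
    overlapping_ids <- character()
  } else {
    overlapping_ids <- unique(
      find_overlaps(enriched, genomic_intervals(reference_enhancers),
                    min_overlap = min_overlap)$id_a
    )
  }
  lgc <- tumor_links |>
    dplyr::group_by(.data$peak_id) |>
    dplyr::summarise(n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop")
  structure(
    list(
      cancer_enriched = enriched,
      cancer_specific = enriched[!enriched$id %in% overlapping_ids, , drop = FALSE],
      reference_overlapping = enriched[enriched$id %in% overlapping_ids, , drop = FALSE],
      linked_gene_count = lgc
    ),
    class = "enhancer_call_set"
  )
}

#' @noRd
#' @exportS3Method base::print
print.enhancer_call_set <- function(x, ...) {
  cat(sprintf("<enhancer_call_set> %d cancer-enriched peaks: %d cancer-specific, %d reference-overlapping\n",
              nrow(x$cancer_enriched), nrow(x$cancer_specific),
              nrow(x$reference_overlapping)))
  invisible(x)
}

#' Regulatory load of cancer-specific vs comparison enhancers
#'
#' Per-peak linked-gene counts are taken from the filtered link table for the
#' cancer-specific peaks and for a comparison peak set (typically
#' non-epithelial distal peaks); the two count distributions are compared
#' with a two-sided Wilcoxon rank-sum test.
#'
#' @param call_set An `enhancer_call_set`.
#' @param links The filtered link tibble (all cell types).
#' @param comparison_peak_ids Character ids of the comparison peaks.
#' @return A list with `per_peak` (tibble: `set`, `peak_id`, `n_genes`),
#'   `summary` (tibble: `set`, `n_peaks`, `mean_genes_per_peak`,
#'   `total_linked_genes`) and `p_value`.
#' @export
regulatory_load <- function(call_set, links, comparison_peak_ids) {
  stopifnot(inherits(call_set, "enhancer_call_set"))
  count_for <- function(ids, set_name) {
    sub <- links[links$peak_id %in% ids, , drop = FALSE]
    sub |>
      dplyr::group_by(.data$peak_id) |>
      dplyr::summarise(n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop") |>
      dplyr::mutate(set = set_name, .before = 1)
  }
  cancer <- count_for(call_set$cancer_specific$id, "cancer_specific")
  comp <- count_for(comparison_peak_ids, "comparison")
  per_peak <- dplyr::bind_rows(cancer, comp)
  total_genes <- function(ids) {
    length(unique(links$gene_id[links$peak_id %in% ids]))
  }
  summary <- tibble::tibble(
    set = c("cancer_specific", "comparison"),
    n_peaks = c(nrow(cancer), nrow(comp)),
    mean_genes_per_peak = c(mean(cancer$n_genes), mean(comp$n_genes)),
    total_linked_genes = c(total_genes(call_set$cancer_specific$id),
                           total_genes(comparison_peak_ids))
  )
  p <- if (nrow(cancer) > 0 && nrow(comp) > 0) {
    if (identical(sort(cancer$n_genes), sort(comp$n_genes))) 1 else
      suppressWarnings(
        stats::wilcox.test(cancer$n_genes, comp$n_genes,
                           alternative = "two.sided")$p.value
      )
  } else {
    NA_real_
  }
  list(per_peak = per_peak, summary = summary, p_value = p)
}

#' Upregulated genes linked to cancer-specific enhancers
#'
#' @param de_results DE tibble from [wilcoxon_de()] (`gene_id`, `log2fc`,
#'   `padj`).
#' @param call_set An `enhancer_call_set`.
#' @param links Filtered link tibble.
#' @param log2fc_min Strict lower bound on log2fc (default 1.0).
#' @param padj_max Strict upper bound on adjusted p (default 0.01).
#' @return A tibble of genes passing both cutoffs and linked to at least one
#'   cancer-specific peak, with their enhancer ids (`gene_id`, `log2fc`,
#'   `padj`, `n_enhancers`, `enhancer_ids`).
#' @export
select_upregulated_linked_genes <- function(de_results, call_set, links,
                                            log2fc_min = 1.0, padj_max = 0.01) {
  stopifnot(inherits(call_set, "enhancer_call_set"))
  up <- de_results[de_results$log2fc > log2fc_min & de_results$padj < padj_max, ,
                   drop = FALSE]
  linked <- links[links$peak_id %in% call_set$cancer_specific$id, , drop = FALSE]
  linked |>
    dplyr::filter(.data$gene_id %in% up$gene_id) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_enhancers = dplyr::n_distinct(.data$peak_id),
      enhancer_ids = paste(sort(unique(.data$peak_id)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::inner_join(up[, c("gene_id", "log2fc", "padj")], by = "gene_id") |>
    dplyr::arrange(.data$padj, dplyr::desc(.data$log2fc)) |>
    dplyr::relocate("gene_id", "log2fc", "padj")
}

#' Super-enhancer candidate genes
#'
#' Flags genes whose promoter is linked to more than `min_links_per_gene`
#' distal peaks that (i) all lie within `span_window` bp of each other and
#' (ii) are mutually correlated in metacell accessibility (median pairwise
#' Pearson r at least `pairwise_r_min`).
#'
#' @param links Filtered link tibble.
#' @param atac_mc Metacells x peaks accessibility matrix (for the pairwise
#'   correlations).
#' @param peaks Interval tibble covering the link peaks.
#' @param min_links_per_gene Strict lower bound on constituent count
#'   (default 5, i.e. "more than five links").
#' @param span_window Maximum constituent span in bp (default 150000).
#' @param pairwise_r_min Median pairwise correlation threshold (default
#'   0.45).
#' @return A tibble: `gene_id`, `n_constituents`, `span_chrom`,
#'   `span_start`, `span_end`, `median_pairwise_r`, `constituent_ids`.
#' @export
superenhancer_candidates <- function(links, atac_mc, peaks,
                                     min_links_per_gene = 5,
                                     span_window = 150000,
                                     pairwise_r_min = 0.45) {
  peaks <- genomic_intervals(peaks)
  by_gene <- split(links$peak_id, links$gene_id)
  rows <- purrr::imap(by_gene, function(pids, gid) {
    pids <- unique(pids)
    if (length(pids) <= min_links_per_gene) return(NULL)
    pk <- peaks[match(pids, peaks$id), , drop = FALSE]
    if (length(unique(pk$chrom)) != 1) return(NULL)
    span_start <- min(pk$start)
    span_end <- max(pk$end)
    if (span_end - span_start > span_window) return(NULL)
    cc <- stats::cor(as.matrix(atac_mc[, pids, drop = FALSE]))
    med_r <- stats::median(cc[upper.tri(cc)])
    if (is.na(med_r) || med_r < pairwise_r_min) return(NULL)
    tibble::tibble(
      gene_id = gid, n_constituents = length(pids),
      span_chrom = pk$chrom[1], span_start = span_start, span_end = span_end,
      median_pairwise_r = med_r,
      constituent_ids = paste(sort(pids), collapse = ";")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(gene_id = character(), n_constituents = integer(),
                          span_chrom = character(), span_start = integer(),
                          span_end = integer(), median_pairwise_r = numeric(),
                          constituent_ids = character()))
  }
  out[order(-out$n_constituents, out$gene_id), , drop = FALSE]
}
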