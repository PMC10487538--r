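#' Benjamini-Hochberg step-up false discovery rates
#'
#' Returns q-values `q_(i) = min_{j >= i}(p_(j) * m / j)` clipped at 1, in the
#' input order. Delegates to [stats::p.adjust()], which implements exactly
#' this step-up rule.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Rank-sum differential expression between two cell groups
#'
#' Reimplements the conventional single-cell two-group marker test: each group
#' is downsampled to at most `max_cells_per_ident` cells (seeded), a gene is
#' tested only when it is detected in at least `min_pct` of the cells of one
#' group, the detection difference is at least `min_diff_pct`, and the
#' absolute log2 fold change is at least `logfc_threshold`. The fold change
#' uses the de-logged-mean convention
#' `log2((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))` on log-normalized
#' expression. P-values come from the two-sided Wilcoxon rank-sum test (exact
#' when both groups are small and untied, normal approximation with tie
#' correction otherwise) and are Benjamini-Hochberg adjusted over the tested
#' genes only.
#'
#' @param expr Cells x genes matrix of log-normalized expression (dense or
#'   sparse), with cell and gene names.
#' @param cells_a,cells_b Disjoint character vectors of cell names (group A is
#'   the "case" whose positive log2fc means upregulation).
#' @param logfc_threshold,min_pct,min_diff_pct Pre-filters (defaults 0.25,
#'   0.5, 0.25).
#' @param max_cells_per_ident Downsampling cap per group (default 500).
#' @param padj_max Only genes with `padj < padj_max` are returned when
#'   `return_all = FALSE` (default 0.01).
#' @param seed Seed for the downsampling.
#' @param return_all Return every tested gene regardless of `padj`?
#' @return A tibble with columns `gene_id`, `log2fc`, `pct_a`, `pct_b`, `p`,
#'   `padj`, ordered by `padj` then `p`.
#' @export
wilcoxon_de <- function(expr, cells_a, cells_b,
                        logfc_threshold = 0.25, min_pct = 0.5,
                        min_diff_pct = 0.25, max_cells_per_ident = 500,
                        padj_max = 0.01, seed = 1L, return_all = FALSE) {
  stopifnot(!is.null(rownames(expr)), !is.null(colnames(expr)))
  cells_a <- intersect(cells_a, rownames(expr))
  cells_b <- intersect(cells_b, rownames(expr))
  if (length(cells_a) == 0 || length(cells_b) == 0) stop("empty group")
  if (length(intersect(cells_a, cells_b)) > 0) stop("groups must be disjoint")
  if (length(cells_a) < 3 || length(cells_b) < 3) stop("each group needs >= 3 cells")
  withr::local_seed(seed)
  if (length(cells_a) > max_cells_per_ident) {
    cells_a <- sample(cells_a, max_cells_per_ident)
  }
  if (length(cells_b) > max_cells_per_ident) {
    cells_b <- sample(cells_b, max_cells_per_ident)
  }
  a <- as.matrix(expr[cells_a, , drop = FALSE])
  b <- as.matrix(expr[cells_b, , drop = FALSE])
  pct_a <- Matrix::colMeans(a > 0)
  pct_b <- Matrix::colMeans(b > 0)
  log2fc <- log2((colMeans(expm1(a)) + 1) / (colMeans(expm1(b)) + 1))
  tested <- pmax(pct_a, pct_b) >= min_pct &
    abs(pct_a - pct_b) >= min_diff_pct &
    abs(log2fc) >= logfc_threshold
  idx <- which(tested)
  p <- vapply(idx, function(j) {
    stats::wilcox.test(a[, j], b[, j], alternative = "two.sided")$p.value
  }, numeric(1))
  out <- tibble::tibble(
    gene_id = colnames(expr)[idx],
    log2fc = log2fc[idx],
    pct_a = unname(pct_a[idx]),
    pct_b = unname(pct_b[idx]),
    p = unname(p),
    padj = benjamini_hochberg(unname(p))
  )
  if (!return_all) out <- out[out$padj < padj_max, , drop = FALSE]
  out[order(out$padj, out$p, out$gene_id), , drop = FALSE]
}

#' Hypergeometric over-representation of gene sets
#'
#' For a query gene list against each set in a collection, computes the
#' upper-tail hypergeometric probability `P(X >= n_overlap)` with universe
#' size `N`, set size `K` and query size `n`, the fold enrichment
#' `(n_overlap/n_query) / (n_set/n_universe)`, and Benjamini-Hochberg
#' q-values across sets.
#'
#' @param query Character vector of genes; must be a subset of `universe`.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]);
#'   members outside the universe are ignored.
#' @param universe Character vector of all eligible genes.
#' @param q_max Report only sets with `q <= q_max` when `return_all = FALSE`
#'   (default 0.01).
#' @param return_all Return every set?
#' @return A tibble with `set_id`, `n_overlap`, `n_query`, `n_set`,
#'   `n_universe`, `fold_enrichment`, `p`, `q`.
#' @export
hypergeom_enrich <- function(query, gene_sets, universe, q_max = 0.01,
                             return_all = FALSE) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop("query genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  n_univ <- length(universe)
  n_query <- length(query)
  rows <- purrr::map(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(members)
    ov <- length(intersect(query, members))
    p <- if (ov == 0) 1 else stats::phyper(ov - 1, k, n_univ - k, n_query, lower.tail = FALSE)
    fold <- if (k == 0 || n_query == 0) NA_real_ else (ov / n_query) / (k / n_univ)
    tibble::tibble(set_id = nm, n_overlap = ov, n_query = n_query,
                   n_set = k, n_universe = n_univ,
                   fold_enrichment = fold, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- benjamini_hochberg(out$p)
  if (!return_all) out <- out[out$q <= q_max, , drop = FALSE]
  out[order(out$q, out$p, out$set_id), , drop = FALSE]
}
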