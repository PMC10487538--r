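#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reduced space into a per-cell tibble
#'
#' @param x A `reduced_space`.
#' @param dims Retained dimensions to include (default all).
#' @param ... Unused.
#' @return A tibble with `cell` and one column per retained dimension.
#' @export
tidy.reduced_space <- function(x, dims = NULL, ...) {
  emb <- reduced_embedding(x, dims)
  out <- tibble::as_tibble(emb)
  dplyr::bind_cols(tibble::tibble(cell = rownames(emb)), out)
}

#' @rdname tidy.reduced_space
#' @export
glance.reduced_space <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_cells = nrow(x$embedding),
    n_dims = ncol(x$embedding),
    n_retained = length(x$retained_dims),
    max_depth_correlation = if (all(is.na(x$depth_correlation))) NA_real_
      else max(abs(x$depth_correlation), na.rm = TRUE)
  )
}

#' Tidy CNV results into per-cell tibbles
#'
#' @param x A `cnv_profile`.
#' @param ... Unused.
#' @return The per-cell score tibble.
#' @export
tidy.cnv_profile <- function(x, ...) x$scores

#' @rdname tidy.cnv_profile
#' @export
glance.cnv_profile <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$residuals),
    n_genes = ncol(x$residuals),
    n_reference = length(x$reference_cells),
    reference_mean_residual = mean(x$residuals[x$reference_cells, ])
  )
}

#' Tidy a metacell grouping into a long membership table
#'
#' @param x A `metacell_grouping`.
#' @param ... Unused.
#' @return A tibble with `metacell` and `cell`.
#' @export
tidy.metacell_grouping <- function(x, ...) {
  tibble::tibble(
    metacell = rep(seq_along(x$groups), lengths(x$groups)),
    cell = x$cells[unlist(x$groups)]
  )
}

#' @rdname tidy.metacell_grouping
#' @export
glance.metacell_grouping <- function(x, ...) {
  ov <- 0L
  if (length(x$groups) > 1) {
    pairs <- utils::combn(length(x$groups), 2)
    ov <- max(apply(pairs, 2, function(p) {
      length(intersect(x$groups[[p[1]]], x$groups[[p[2]]]))
    }))
  }
  tibble::tibble(n_groups = length(x$groups), k = x$k,
                 max_shared_observed = ov, max_shared_allowed = x$max_shared)
}

#' Tidy an enhancer call set into a per-peak tibble
#'
#' @param x An `enhancer_call_set`.
#' @param ... Unused.
#' @return A tibble with `peak_id`, `set` and `n_linked_genes`.
#' @export
tidy.enhancer_call_set <- function(x, ...) {
  out <- tibble::tibble(
    peak_id = x$cancer_enriched$id,
    set = ifelse(x$cancer_enriched$id %in% x$cancer_specific$id,
                 "cancer_specific", "reference_overlapping")
  )
  out$n_linked_genes <- x$linked_gene_count$n_genes[
    match(out$peak_id, x$linked_gene_count$peak_id)]
  out
}

#' @rdname tidy.enhancer_call_set
#' @export
glance.enhancer_call_set <- function(x, ...) {
  tibble::tibble(
    n_cancer_enriched = nrow(x$cancer_enriched),
    n_cancer_specific = nrow(x$cancer_specific),
    n_reference_overlapping = nrow(x$reference_overlapping)
  )
}

#' Tidy a PWM into a long position-probability tibble
#'
#' @param x A `pwm`.
#' @param ... Unused.
#' @return A tibble with `position`, `base`, `probability`, `score_bits`.
#' @export
tidy.pwm <- function(x, ...) {
  w <- pwm_width(x)
  sm <- pwm_score_matrix(x)
  tibble::tibble(
    position = rep(seq_len(w), each = 4),
    base = rep(rownames(x$probs), w),
    probability = as.vector(x$probs),
    score_bits = as.vector(sm)
  )
}
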