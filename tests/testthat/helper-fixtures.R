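# Shared fixtures, memoized across test files. Everything is generated in
# code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small matched cohort for unit tests (fast: ~5 s)
small_cohort <- function() {
  memo("small_cohort", generate_cohort(cohort_config(n_cells_per_sample = 150,
                                                     seed = 101)))
}

# full default fixture runs for the acceptance suite, one per seed
acceptance_cohort <- function(seed) {
  memo(paste0("cohort_", seed), generate_cohort(cohort_config(seed = seed)))
}

acceptance_run <- function(seed) {
  memo(paste0("run_", seed),
       run_pipeline(acceptance_cohort(seed), seed = seed))
}

# deterministic random interval set
random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             max_pos = 100000, width_range = c(50, 800)) {
  withr::with_seed(seed, {
    start <- sample.int(max_pos, n, replace = TRUE)
    width <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
    tibble::tibble(
      chrom = sample(chroms, n, replace = TRUE),
      start = start,
      end = start + width,
      id = paste0("iv", seq_len(n)),
      score = stats::runif(n)
    )
  })
}

# all-pairs interval overlap oracle
overlap_oracle <- function(a, b, min_overlap = 1) {
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          id_a = a$id[i], id_b = b$id[j], overlap_bp = as.integer(ov)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          overlap_bp = integer()))
  }
  out[order(out$id_a, out$id_b), ]
}

# naive O(m^2) Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    q[i] <- min(1, min(p[ord[rank_i:m]] * m / (rank_i:m)))
  }
  q
}

# exact two-sided rank-sum p by exhaustive enumeration (no ties)
wilcox_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  one_tail <- if (u_obs > mu) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(2 * one_tail, 1)
}

# exact hypergeometric upper tail by summation
hyper_oracle <- function(overlap, n_set, n_universe, n_query) {
  if (overlap == 0) return(1)
  kmax <- min(n_set, n_query)
  sum(vapply(overlap:kmax, function(k) {
    exp(lchoose(n_set, k) + lchoose(n_universe - n_set, n_query - k) -
          lchoose(n_universe, n_query))
  }, numeric(1)))
}
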