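# width-8 near-consensus motif (consensus ACGTTGCA); narrow motifs cannot
# reach small p-values, so tests use a realistic width
make_test_pwm <- function(id = "TF1", cols = NULL, pc = 0) {
  if (is.null(cols)) {
    base <- diag(4) * 0.8 + 0.05
    cols <- base[, c(1, 2, 3, 4, 4, 3, 2, 1)]
  }
  pwm(cols, motif_id = id, pseudocount = pc)
}
test_consensus <- "ACGTTGCA"

test_that("MEME files parse and round trip to 1e-6", {
  p1 <- make_test_pwm("M1")
  p2 <- pwm(matrix(0.25, 4, 3), "M2")
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(p1, p2), path)
  back <- read_meme(path, pseudocount = 0)
  expect_named(back, c("M1", "M2"))
  expect_equal(back$M1$probs, p1$probs, tolerance = 1e-6)
  expect_equal(pwm_width(back$M2), 3)

  bad <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "ALPHABET= ACGU", "MOTIF X"), bad)
  expect_error(read_meme(bad), "alphabet")
})

test_that("PWM scores behave at the extremes", {
  x <- make_test_pwm()
  expect_equal(pwm_consensus(x), test_consensus)
  sm <- pwm_score_matrix(x)
  # consensus sequence achieves the maximal possible score
  expect_equal(sum(apply(sm, 2, max)),
               sum(sm[cbind(match(strsplit(test_consensus, "")[[1]],
                                  c("A", "C", "G", "T")), 1:8)]))
  flat <- pwm(matrix(0.25, 4, 4), "flat")
  hits <- scan_motifs(flat, c(s = "ACGTACGTAC"), p_max = 1)
  expect_true(all(abs(hits$score) < 1e-12))
})

test_that("the score-distribution DP equals brute-force enumeration over all windows", {
  for (w in c(4, 6)) {
    withr::with_seed(w, {
      cols <- matrix(rgamma(4 * w, 1), 4, w)
      cols <- sweep(cols, 2, colSums(cols), "/")
    })
    x <- pwm(cols, "rnd", pseudocount = 1e-3)
    dist <- pwm_score_distribution(x, granularity = 1e-3)
    expect_equal(sum(dist$prob), 1, tolerance = 1e-9)
    # enumerate all 4^w sequences
    grid <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- grid %*% rep(0, w)
    for (i in seq_len(w)) scores <- scores + dist$int_scores[cbind(grid[, i], i)]
    probs <- apply(grid, 1, function(g) prod(x$background[g]))
    for (s in sample(dist$support, 25)) {
      expect_equal(dist$tail[s - dist$support[1] + 1],
                   sum(probs[scores >= s]), tolerance = 1e-9)
    }
  }
})

test_that("planted consensus sites are recovered and shuffled sequences stay clean", {
  x <- make_test_pwm("PLANT")
  for (s in 1:3) {
    withr::with_seed(500 + s, {
      seqs <- vapply(1:30, function(i) {
        paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
      }, "")
    })
    names(seqs) <- paste0("seq", 1:30)
    offsets <- rep(c(5L, 20L, 40L), length.out = 30)
    planted <- vapply(seq_along(seqs), function(i) {
      paste0(substr(seqs[i], 1, offsets[i]), test_consensus,
             substr(seqs[i], offsets[i] + 9, 60))
    }, "")
    names(planted) <- names(seqs)
    hits <- scan_motifs(x, planted, q_max = 0.01)
    found <- paste(hits$sequence_id, hits$offset)
    expect_true(all(paste(names(seqs), offsets) %in% found))
    # shuffled (plain random) sequences: no significant hits
    null_hits <- scan_motifs(x, seqs, q_max = 0.01)
    expect_equal(nrow(null_hits), 0)
  }
})

test_that("scanning is reverse-complement symmetric", {
  x <- make_test_pwm()
  seqs <- c(a = "ACGTACGTAAACGTATTTGCA", b = "GGGACGTACCCACGTAGG")
  rc <- vapply(seqs, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, "")
  fwd <- scan_motifs(x, seqs, p_max = 1)
  rev_ <- scan_motifs(x, rc, p_max = 1)
  flip <- function(h, lens) {
    h$offset <- unname(lens[h$sequence_id]) - pwm_width(x) - h$offset
    h$strand <- ifelse(h$strand == "+", "-", "+")
    h[order(h$sequence_id, h$offset, h$strand), ]
  }
  lens <- nchar(seqs)
  flipped <- flip(rev_, lens)
  fwd <- fwd[order(fwd$sequence_id, fwd$offset, fwd$strand), ]
  expect_equal(fwd$offset, flipped$offset)
  expect_equal(fwd$score, flipped$score, tolerance = 1e-12)
  expect_equal(fwd$p, flipped$p, tolerance = 1e-12)
})

test_that("windows containing N are skipped and short sequences give no windows", {
  x <- make_test_pwm()
  hits <- scan_motifs(x, c(s = "ACNTA"), p_max = 1)
  expect_equal(nrow(hits), 0)
  expect_equal(nrow(scan_motifs(x, c(s = "ACg"), p_max = 1)), 0)
})

test_that("significant motifs rank by transcription-factor expression", {
  x1 <- make_test_pwm("TFLOW")
  x2 <- make_test_pwm("TFHIGH")
  seqs <- c(s1 = "TTTACGTTGCATTTTTTTTTTTT")
  hits <- scan_motifs(list(x1, x2), seqs, p_max = 1e-3)
  hits$q <- 0.001  # both significant
  ranked <- rank_hits_by_tf_expression(hits, c(TFHIGH = 10, TFLOW = 2))
  expect_equal(ranked$motif_id, c("TFHIGH", "TFLOW"))
  missing_tf <- rank_hits_by_tf_expression(hits, c(TFHIGH = 10))
  expect_equal(missing_tf$motif_id[2], "TFLOW")
  expect_false(missing_tf$tf_measured[2])
  none <- rank_hits_by_tf_expression(hits[0, ], c(TFHIGH = 10))
  expect_equal(nrow(none), 0)
})

test_that("motif enrichment separates constructed target and background sets", {
  x <- make_test_pwm("ENR")
  withr::with_seed(77, {
    bg <- vapply(1:40, function(i) {
      paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE,
                   prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    }, "")
  })
  names(bg) <- paste0("b", 1:40)
  tg <- vapply(bg[1:40], function(s) {
    paste0(substr(s, 1, 20), test_consensus, substr(s, 29, 50))
  }, "")
  names(tg) <- paste0("t", 1:40)
  res <- motif_enrichment(tg, bg, list(x), return_all = TRUE)
  expect_true(res$enriched[1])
  expect_equal(res$target_with_motif, 40)
  expect_gt(res$log2fc, 1)
  # p agrees with the exact hypergeometric oracle
  want <- hyper_oracle(res$target_with_motif,
                       res$target_with_motif + res$background_with_motif,
                       80, 40)
  expect_equal(res$p, want, tolerance = 1e-12)
  # identical sets are never reported
  same <- motif_enrichment(bg, bg, list(x), return_all = TRUE)
  expect_equal(same$log2fc, 0)
  expect_false(same$enriched)
})
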