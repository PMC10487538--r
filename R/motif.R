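#' Position weight matrices
#'
#' A `pwm` holds a 4 x w position-probability matrix over A,C,G,T (columns
#' sum to one), a background distribution and the pseudocount that was mixed
#' in. Scores are log2 odds (bits): `log2(p_i(base) / bg(base))`.
#'
#' @param probs 4 x w numeric matrix, rows A, C, G, T.
#' @param motif_id Motif identifier.
#' @param background Length-4 background probabilities (default uniform).
#' @param pseudocount Mixed into the probabilities as
#'   `(p + pc * bg) / (1 + pc)` (default 0, i.e. taken as given).
#' @return A `pwm` object.
#' @export
pwm <- function(probs, motif_id = "motif", background = rep(0.25, 4),
                pseudocount = 0) {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == 4, all(probs >= 0))
  if (any(abs(colSums(probs) - 1) > 1e-6)) stop("PWM columns must sum to 1")
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-6)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount > 0) {
    probs <- (probs + pseudocount * background) / (1 + pseudocount)
  }
  rownames(probs) <- names(background) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, probs = probs,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @noRd
#' @exportS3Method base::print
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: width %d, consensus %s\n",
              x$motif_id, ncol(x$probs), pwm_consensus(x)))
  invisible(x)
}

#' @param x A `pwm`.
#' @rdname pwm
#' @export
pwm_width <- function(x) ncol(x$probs)

#' @rdname pwm
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$probs)[apply(x$probs, 2, which.max)], collapse = "")
}

#' Log2-odds score matrix of a PWM
#'
#' @param x A `pwm`.
#' @return 4 x w matrix of `log2(p / bg)` in bits.
#' @export
pwm_score_matrix <- function(x) {
  log2(x$probs / x$background)
}

#' Read and write motifs in MEME minimal format
#'
#' Parses the letter-probability matrices of a MEME-format motif file
#' (alphabet must be ACGT); the stated background letter frequencies are
#' used when present, otherwise uniform. A pseudocount can be mixed in on
#' load.
#'
#' @param path Path to a MEME-format file.
#' @param pseudocount Pseudocount applied on load (default 1e-3).
#' @return A list of `pwm` objects, named by motif id.
#' @export
read_meme <- function(path, pseudocount = 1e-3) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  alpha_line <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha_line) > 0) {
    alpha <- gsub("^ALPHABET\\s*=?\\s*", "", alpha_line[1])
    if (gsub("\\s", "", alpha) != "ACGT") {
      stop("unsupported alphabet: ", alpha, " (only ACGT is supported)")
    }
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0 && bg_at[1] < length(lines)) {
    bg_fields <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(bg_fields[c(FALSE, TRUE)]))
    letters_bg <- bg_fields[c(TRUE, FALSE)]
    if (!anyNA(vals) && identical(letters_bg, c("A", "C", "G", "T"))) {
      background <- vals / sum(vals)
    }
  }
  motif_at <- grep("^MOTIF\\s", lines)
  if (length(motif_at) == 0) stop("no MOTIF entries in ", path)
  out <- list()
  for (m in motif_at) {
    id <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    hdr_rel <- grep("^letter-probability matrix", lines[seq(m, length(lines))])
    if (length(hdr_rel) == 0) stop("motif ", id, " lacks a letter-probability matrix")
    hdr <- m + hdr_rel[1] - 1
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[hdr]))
    if (is.na(w)) stop("cannot parse width for motif ", id)
    rows <- lines[(hdr + 1):(hdr + w)]
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    if (any(lengths(vals) != 4) || anyNA(unlist(vals))) {
      stop("malformed probability rows for motif ", id)
    }
    probs <- t(do.call(rbind, vals))
    probs <- sweep(probs, 2, colSums(probs), "/")
    out[[id]] <- pwm(probs, motif_id = id, background = background,
                     pseudocount = pseudocount)
  }
  out
}

#' @param pwms A list of `pwm` objects.
#' @rdname read_meme
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]), ""
  )
  for (p in pwms) {
    lines <- c(lines,
      paste("MOTIF", p$motif_id),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
              pwm_width(p)),
      apply(p$probs, 2, function(col) sprintf("%.6f %.6f %.6f %.6f",
                                              col[1], col[2], col[3], col[4])),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Exact null distribution of discretized PWM scores
#'
#' Dynamic program over motif positions: per-position log2-odds scores are
#' discretized to integer multiples of `granularity` bits and convolved
#' under the background base distribution, giving the exact probability of
#' every achievable integer score and hence exact upper-tail p-values for
#' the discretized scores.
#'
#' @param x A `pwm`.
#' @param granularity Discretization step in bits (default 1/1000).
#' @return A list with `int_scores` (4 x w integer matrix), `support`
#'   (integer vector of achievable sums), `prob` (their probabilities) and
#'   `tail` (`P(score >= support)`), plus the granularity.
#' @export
pwm_score_distribution <- function(x, granularity = 1e-3) {
  s_int <- round(pwm_score_matrix(x) / granularity)
  storage.mode(s_int) <- "integer"
  w <- ncol(s_int)
  bg <- x$background
  lo_tot <- sum(apply(s_int, 2, min))
  hi_tot <- sum(apply(s_int, 2, max))
  width <- hi_tot - lo_tot + 1
  dp <- numeric(width)
  offset_lo <- 0L  # running minimum achievable sum
  dp[1] <- 1
  cur_len <- 1L
  for (i in seq_len(w)) {
    col <- s_int[, i]
    new_lo <- offset_lo + min(col)
    new_len <- cur_len + (max(col) - min(col))
    new_dp <- numeric(new_len)
    for (b in 1:4) {
      shift <- (offset_lo + col[b]) - new_lo
      idx <- seq_len(cur_len)
      new_dp[idx + shift] <- new_dp[idx + shift] + bg[b] * dp[idx]
    }
    dp <- new_dp
    cur_len <- new_len
    offset_lo <- new_lo
  }
  support <- seq.int(offset_lo, offset_lo + cur_len - 1L)
  tail <- rev(cumsum(rev(dp)))
  list(int_scores = s_int, support = support, prob = dp, tail = pmin(tail, 1),
       granularity = granularity)
}

encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  code  # NA for N or anything else
}

revcomp_code <- function(code) rev(5L - code)

scan_one <- function(code, dist) {
  w <- ncol(dist$int_scores)
  n <- length(code)
  nw <- n - w + 1
  if (nw < 1) return(integer(0))
  s <- integer(nw)
  bad <- logical(nw)
  for (i in seq_len(w)) {
    ci <- code[i:(i + nw - 1)]
    bad <- bad | is.na(ci)
    ci[is.na(ci)] <- 1L
    s <- s + dist$int_scores[cbind(ci, i)]
  }
  s[bad] <- NA_integer_
  s
}

#' Scan sequences for motif occurrences with exact p-values
#'
#' Every window of width w on both strands is scored with the PWM log2-odds;
#' the per-window p-value is the exact upper tail of the discretized null
#' score distribution ([pwm_score_distribution()]) and q-values are
#' Benjamini-Hochberg over all windows scanned in the call. Windows
#' containing N are skipped. Offsets are 0-based on the forward strand of
#' the input sequence.
#'
#' @param pwms A `pwm` or list of `pwm`s.
#' @param sequences Named character vector of DNA sequences.
#' @param both_strands Scan the reverse complement too (default TRUE)?
#' @param granularity Score discretization in bits (default 1/1000).
#' @param p_max Report only windows with `p <= p_max` (default 1e-4);
#'   q-values are still computed over all windows.
#' @param q_max Optional additional filter on q.
#' @return A tibble of hits: `motif_id`, `sequence_id`, `offset`, `strand`,
#'   `score` (bits), `p`, `q`.
#' @export
scan_motifs <- function(pwms, sequences, both_strands = TRUE,
                        granularity = 1e-3, p_max = 1e-4, q_max = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(length(sequences) > 0, !is.null(names(sequences)))
  codes <- lapply(sequences, encode_dna)
  all_rows <- list()
  for (x in pwms) {
    dist <- pwm_score_distribution(x, granularity)
    w <- ncol(dist$int_scores)
    tail_p <- function(s_int) {
      idx <- s_int - dist$support[1] + 1L
      idx <- pmin(pmax(idx, 1L), length(dist$tail))
      p <- dist$tail[idx]
      p[s_int > dist$support[length(dist$support)]] <- 0
      p[s_int < dist$support[1]] <- 1
      p
    }
    for (sid in names(codes)) {
      code <- codes[[sid]]
      n <- length(code)
      strands <- if (both_strands) c("+", "-") else "+"
      for (st in strands) {
        cc <- if (st == "+") code else revcomp_code(code)
        s <- scan_one(cc, dist)
        ok <- which(!is.na(s))
        if (length(ok) == 0) next
        offset <- if (st == "+") ok - 1L else n - w - (ok - 1L)
        all_rows[[length(all_rows) + 1]] <- tibble::tibble(
          motif_id = x$motif_id, sequence_id = sid,
          offset = as.integer(offset), strand = st,
          score = s[ok] * granularity,
          p = tail_p(s[ok])
        )
      }
    }
  }
  hits <- dplyr::bind_rows(all_rows)
  if (nrow(hits) == 0) {
    return(tibble::tibble(motif_id = character(), sequence_id = character(),
                          offset = integer(), strand = character(),
                          score = numeric(), p = numeric(), q = numeric()))
  }
  hits$q <- benjamini_hochberg(hits$p)
  hits <- hits[hits$p <= p_max, , drop = FALSE]
  if (!is.null(q_max)) hits <- hits[hits$q < q_max, , drop = FALSE]
  hits[order(hits$motif_id, hits$sequence_id, hits$offset, hits$strand), ,
       drop = FALSE]
}

#' Rank significant motifs by transcription-factor expression
#'
#' Motifs with at least one hit at `q < q_max` are ordered by the summed
#' log-normalized expression of their transcription factor in the malignant
#' cells; motifs whose TF is absent from the expression vector rank last and
#' are flagged.
#'
#' @param hits Hit tibble from [scan_motifs()].
#' @param tf_expression Named numeric vector: gene -> summed log-normalized
#'   expression over malignant cells.
#' @param motif_tf Optional named character vector mapping motif id to TF
#'   gene; by default the motif id is the TF gene.
#' @param q_max Significance threshold (default 0.01).
#' @return A tibble: `motif_id`, `tf`, `tf_expression`, `n_hits`, `best_q`,
#'   `tf_measured`, ordered by expression (measured first).
#' @export
rank_hits_by_tf_expression <- function(hits, tf_expression, motif_tf = NULL,
                                       q_max = 0.01) {
  sig <- hits[hits$q < q_max, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble::tibble(motif_id = character(), tf = character(),
                          tf_expression = numeric(), n_hits = integer(),
                          best_q = numeric(), tf_measured = logical()))
  }
  per_motif <- sig |>
    dplyr::group_by(.data$motif_id) |>
    dplyr::summarise(n_hits = dplyr::n(), best_q = min(.data$q), .groups = "drop")
  tf <- if (is.null(motif_tf)) per_motif$motif_id else unname(motif_tf[per_motif$motif_id])
  per_motif$tf <- tf
  per_motif$tf_measured <- per_motif$tf %in% names(tf_expression)
  per_motif$tf_expression <- ifelse(per_motif$tf_measured,
                                    tf_expression[per_motif$tf], NA_real_)
  per_motif <- per_motif[order(-per_motif$tf_measured,
                               -ifelse(is.na(per_motif$tf_expression), -Inf,
                                       per_motif$tf_expression),
                               per_motif$motif_id), , drop = FALSE]
  per_motif[, c("motif_id", "tf", "tf_expression", "n_hits", "best_q",
                "tf_measured")]
}

#' Motif enrichment between two sequence sets
#'
#' A sequence "contains" a motif when at least one window passes the
#' per-window score threshold (`hit_p_max`). Containment counts in target vs
#' background are tested with the upper-tail hypergeometric (universe =
#' target + background sequences) and effect size
#' `log2fc = log2(((t+1)/(n_t+1)) / ((b+1)/(n_b+1)))` with a +1 pseudocount
#' on counts. Motifs passing `q < fdr_max` and `log2fc > log2fc_min` are
#' reported.
#'
#' @param target_seqs,background_seqs Named character vectors of sequences.
#' @param pwms List of `pwm`s.
#' @param fdr_max,log2fc_min Reporting cutoffs (defaults 0.01 and 1.0).
#' @param hit_p_max Per-window p-value defining containment (default 1e-4).
#' @param granularity Score discretization (default 1/1000).
#' @param return_all Return every motif with an `enriched` flag?
#' @return A tibble: `motif_id`, `n_target`, `n_background`,
#'   `target_with_motif`, `background_with_motif`, `log2fc`, `p`, `q`
#'   (and `enriched` when `return_all`).
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwms,
                             fdr_max = 0.01, log2fc_min = 1.0,
                             hit_p_max = 1e-4, granularity = 1e-3,
                             return_all = FALSE) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  n_t <- length(target_seqs)
  n_b <- length(background_seqs)
  stopifnot(n_t > 0, n_b > 0)
  all_seqs <- c(target_seqs, background_seqs)
  names(all_seqs) <- c(paste0("t|", names(target_seqs)),
                       paste0("b|", names(background_seqs)))
  hits <- scan_motifs(pwms, all_seqs, p_max = hit_p_max,
                      granularity = granularity)
  rows <- purrr::map(pwms, function(x) {
    h <- hits[hits$motif_id == x$motif_id, , drop = FALSE]
    with_motif <- unique(h$sequence_id)
    t_ov <- sum(startsWith(with_motif, "t|"))
    b_ov <- sum(startsWith(with_motif, "b|"))
    k_total <- t_ov + b_ov
    p <- if (t_ov == 0) 1 else
      stats::phyper(t_ov - 1, k_total, n_t + n_b - k_total, n_t, lower.tail = FALSE)
    tibble::tibble(
      motif_id = x$motif_id, n_target = n_t, n_background = n_b,
      target_with_motif = t_ov, background_with_motif = b_ov,
      log2fc = log2(((t_ov + 1) / (n_t + 1)) / ((b_ov + 1) / (n_b + 1))),
      p = p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- benjamini_hochberg(out$p)
  out$enriched <- out$q < fdr_max & out$log2fc > log2fc_min
  out <- out[order(out$q, -out$log2fc, out$motif_id), , drop = FALSE]
  if (!return_all) {
    out <- out[out$enriched, , drop = FALSE]
    out$enriched <- NULL
  }
  out
}
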