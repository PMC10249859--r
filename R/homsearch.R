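# Self-contained local homology search. A seed-and-extend scanner stands in
# for BLASTn: exact-match word seeds locate candidate regions, which are then
# resolved by exact affine-gap Smith-Waterman alignment of the query against
# the seeded window, with Karlin-Altschul E-values for significance.

#' Alignment scoring scheme
#'
#' Megablast-style nucleotide scoring: match +2, mismatch -3, affine gaps
#' (a gap of length k costs `gap_open + k * gap_extend`). The Karlin-Altschul
#' constants convert raw scores into E-values via
#' `E = K * m * n * exp(-lambda * S)`; the defaults are the tabulated values
#' for this scoring scheme and can be re-estimated with [calibrate_karlin()].
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open,gap_extend affine gap costs (>= 0, subtracted).
#' @param karlin_lambda,karlin_K Karlin-Altschul constants (> 0).
#' @return list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2, mismatch = -3,
                              gap_open = 5, gap_extend = 2,
                              karlin_lambda = 0.625, karlin_K = 0.41) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            karlin_lambda > 0, karlin_K > 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_K = karlin_K),
            class = "alignment_scoring")
}

sw_raw <- function(query, subject, scoring) {
  sw_align_cpp(query, subject, as.integer(scoring$match),
               as.integer(scoring$mismatch),
               as.integer(scoring$gap_open), as.integer(scoring$gap_extend))
}

#' Optimal local alignment (Smith-Waterman oracle)
#'
#' Exact affine-gap local alignment by dynamic programming. Intended as the
#' ground-truth oracle for the heuristic scanner; both sequences are limited
#' to 100 kb. The search is forward-orientation; pass `strand = "-"` to
#' align the query against the reverse complement of the subject (subject
#' coordinates are reported on the forward strand).
#'
#' @param query,subject DNA strings.
#' @param scoring an [alignment_scoring()] scheme.
#' @param strand `"+"` or `"-"`.
#' @return a one-row hit table (class `numt_hits`), or `NULL` when no
#'   positive-scoring alignment exists. Gapped rows are stored in query
#'   orientation: ungapping `q_gapped` reproduces `query[q_start:q_end)`;
#'   for minus-strand hits `s_gapped` is the reverse complement of the
#'   subject interval.
#' @examples
#' h <- smith_waterman("ACGTACGT", "TTTACGTACGTTT")
#' h$score  # 16
#' @export
smith_waterman <- function(query, subject, scoring = alignment_scoring(),
                           strand = "+") {
  if (nchar(query) > 1e5 || nchar(subject) > 1e5)
    stop("sequence longer than 100 kb; the exact aligner is for validation")
  subj <- if (strand == "-") revcomp(subject) else subject
  a <- sw_raw(query, subj, scoring)
  if (a$score <= 0) return(NULL)
  n <- nchar(subject)
  s_start <- if (strand == "-") n - a$s_end else a$s_start
  s_end <- if (strand == "-") n - a$s_start else a$s_end
  as_hit_table(data.frame(
    query_id = "query", scaffold_id = "subject", strand = strand,
    q_start = a$q_start, q_end = a$q_end,
    s_start = s_start, s_end = s_end,
    aligned_len = a$aligned_len, matches = a$matches,
    identity = a$identity, score = a$score, evalue = NA_real_,
    q_gapped = a$q_gapped, s_gapped = a$s_gapped,
    stringsAsFactors = FALSE))
}

# cluster surviving ungapped HSPs into candidate subject windows
seed_windows <- function(hsps, slen, gap = 300L, margin = 200L) {
  if (nrow(hsps) == 0) return(NULL)
  o <- order(hsps[, "s_lo"])
  lo <- hsps[o, "s_lo"]; hi <- hsps[o, "s_hi"]
  out <- list()
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] > cur_hi + gap) {
      out[[length(out) + 1L]] <- c(max(0L, cur_lo - margin),
                                   min(slen, cur_hi + margin))
      cur_lo <- lo[k]; cur_hi <- hi[k]
    } else cur_hi <- max(cur_hi, hi[k])
  }
  out[[length(out) + 1L]] <- c(max(0L, cur_lo - margin),
                               min(slen, cur_hi + margin))
  out
}

# Extend a core alignment's span outward without gaps while the cumulative
# extension score stays above -tol. The optimal local alignment ends at
# the maximum-scoring cell, which systematically undershoots the true
# homology boundary when the terminal bases are diverged; the bounded
# net-negative extension recovers those bases, while random background
# beyond the boundary exhausts the tolerance within a few columns.
extend_hit_span <- function(query, subject, a, tol = 6, limit = 15L) {
  m <- nchar(query); n <- nchar(subject)
  ext_one <- function(pos_q, pos_s, dir) {
    cum <- 0; k <- 0L; qa <- character(0); sa <- character(0)
    while (k < limit) {
      qi <- pos_q + dir * (k + 1L); si <- pos_s + dir * (k + 1L)
      if (qi < 1L || qi > m || si < 1L || si > n) break
      qb <- substr(query, qi, qi); sb <- substr(subject, si, si)
      cum <- cum + if (qb == sb && qb != "N") 2 else -3
      if (cum < -tol) break
      k <- k + 1L
      if (dir > 0) { qa <- c(qa, qb); sa <- c(sa, sb) }
      else { qa <- c(qb, qa); sa <- c(sb, sa) }
    }
    list(k = k, q = paste(qa, collapse = ""), s = paste(sa, collapse = ""))
  }
  left <- ext_one(a$q_start + 1L, a$s_start + 1L, -1L)   # 1-based walk
  right <- ext_one(a$q_end, a$s_end, 1L)
  if (left$k == 0 && right$k == 0) return(a)
  a$q_start <- a$q_start - left$k; a$s_start <- a$s_start - left$k
  a$q_end <- a$q_end + right$k; a$s_end <- a$s_end + right$k
  a$q_gapped <- paste0(left$q, a$q_gapped, right$q)
  a$s_gapped <- paste0(left$s, a$s_gapped, right$s)
  qv <- strsplit(a$q_gapped, "", fixed = TRUE)[[1]]
  sv <- strsplit(a$s_gapped, "", fixed = TRUE)[[1]]
  ok <- qv != "-" & sv != "-" & qv != "N" & sv != "N"
  a$aligned_len <- length(qv)
  a$matches <- sum(qv[ok] == sv[ok])
  a$identity <- if (any(ok)) a$matches / sum(ok) else 0
  a
}

# align a query into a subject window, then recurse into the flanks so
# several nearby insertions sharing one window each yield a hit;
# min_score prunes alignments the E-value filter would drop anyway
align_window <- function(query, subj_or, w1, w2, scoring, min_len,
                         min_score, depth = 0L) {
  if (w2 - w1 < min_len || depth > 12L) return(list())
  a <- sw_raw(query, substr(subj_or, w1 + 1L, w2), scoring)
  if (a$score < min_score) return(list())
  a$s_start <- w1 + a$s_start
  a$s_end <- w1 + a$s_end
  c(list(a),
    align_window(query, subj_or, w1, a$s_start, scoring, min_len,
                 min_score, depth + 1L),
    align_window(query, subj_or, a$s_end, w2, scoring, min_len,
                 min_score, depth + 1L))
}

#' Scan an assembly for local hits of a query
#'
#' Seed-and-extend search of both strands: exact-match word seeds are
#' extended without gaps under an X-drop rule, surviving high-scoring
#' segments delimit candidate windows, and each window is resolved by exact
#' affine local alignment (re-aligning the flanks, so several nearby
#' insertions sharing a window each yield a hit). Hits are kept when
#' `aligned_len >= min_len`, `identity >= min_identity` and
#' `evalue <= max_evalue`, with `E = K * m * n * exp(-lambda * S)`
#' (m = query length, n = total scaffold length). Same-scaffold,
#' same-strand hits whose subject intervals overlap by more than half of
#' the shorter interval are merged, keeping the higher-scoring one, so a
#' single insertion yields a single hit.
#'
#' @param query DNA string (100-2,000 bp).
#' @param scaffolds a [scaffold_set()].
#' @param scoring an [alignment_scoring()].
#' @param min_len minimum aligned length in bp.
#' @param min_identity minimum identity fraction.
#' @param max_evalue E-value ceiling.
#' @param word_size exact-match seed length.
#' @param xdrop score drop terminating ungapped seed extension.
#' @param min_ungapped minimum ungapped extension score for a seed to
#'   spawn a window.
#' @param query_id identifier written into the hit table.
#' @return a hit table (class `numt_hits`), possibly empty.
#' @export
find_hits <- function(query, scaffolds, scoring = alignment_scoring(),
                      min_len = 100, min_identity = 0.60, max_evalue = 1e-4,
                      word_size = 9L, xdrop = 15L, min_ungapped = 25L,
                      query_id = "query") {
  qlen <- nchar(query)
  if (qlen < 100 || qlen > 2000)
    stop("query length must lie in [100, 2000]")
  if (nrow(scaffolds) == 0) return(empty_hit_table())
  n_total <- sum(nchar(scaffolds$sequence))
  # raw score below which the E-value filter rejects in any case
  min_score <- max(1, ceiling(log(scoring$karlin_K * qlen * n_total /
                                    max_evalue) / scoring$karlin_lambda))
  rows <- list()
  for (si in seq_len(nrow(scaffolds))) {
    subj <- scaffolds$sequence[si]
    slen <- nchar(subj)
    for (strand in c("+", "-")) {
      subj_or <- if (strand == "-") revcomp(subj) else subj
      hsps <- seed_scan_cpp(query, subj_or, as.integer(word_size),
                            as.integer(scoring$match),
                            as.integer(scoring$mismatch),
                            as.integer(xdrop), as.integer(min_ungapped))
      wins <- seed_windows(hsps, slen)
      for (w in wins) {
        alns <- align_window(query, subj_or, w[1], w[2], scoring,
                             min_len, min_score)
        for (a in alns) {
          a <- extend_hit_span(query, subj_or, a)
          ev <- scoring$karlin_K * qlen * n_total *
            exp(-scoring$karlin_lambda * a$score)
          s_start_or <- a$s_start
          s_end_or <- a$s_end
          if (strand == "-") {
            tmp <- s_start_or
            s_start_or <- slen - s_end_or
            s_end_or <- slen - tmp
          }
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = query_id, scaffold_id = scaffolds$id[si],
            strand = strand,
            q_start = a$q_start, q_end = a$q_end,
            s_start = s_start_or, s_end = s_end_or,
            aligned_len = a$aligned_len, matches = a$matches,
            identity = a$identity, score = a$score, evalue = ev,
            q_gapped = a$q_gapped, s_gapped = a$s_gapped,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_hit_table())
  hits <- do.call(rbind, rows)
  hits <- hits[hits$aligned_len >= min_len &
               hits$identity >= min_identity &
               hits$evalue <= max_evalue, , drop = FALSE]
  hits <- merge_overlapping_hits(hits)
  hits <- hits[order(hits$scaffold_id, hits$s_start), , drop = FALSE]
  rownames(hits) <- NULL
  as_hit_table(hits)
}

# keep the higher-scoring hit when two same-scaffold/strand subject
# intervals overlap by > 50% of the shorter
merge_overlapping_hits <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  keep <- rep(TRUE, nrow(hits))
  o <- order(-hits$score)
  for (a_i in seq_along(o)) {
    i <- o[a_i]
    if (!keep[i]) next
    for (b_i in seq_along(o)) {
      if (b_i <= a_i) next
      j <- o[b_i]
      if (!keep[j]) next
      if (hits$scaffold_id[i] != hits$scaffold_id[j] ||
          hits$strand[i] != hits$strand[j]) next
      ov <- min(hits$s_end[i], hits$s_end[j]) -
        max(hits$s_start[i], hits$s_start[j])
      shorter <- min(hits$s_end[i] - hits$s_start[i],
                     hits$s_end[j] - hits$s_start[j])
      if (ov > 0.5 * shorter) keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Estimate Karlin-Altschul constants by simulation
#'
#' Draws random sequence pairs, computes their optimal local alignment
#' scores, and fits the Gumbel (extreme-value) law those scores follow:
#' lambda from the method of moments (`pi / (sd * sqrt(6))`) and K from the
#' fitted location parameter.
#'
#' @param scoring an [alignment_scoring()].
#' @param seed integer seed.
#' @param n_pairs number of random sequence pairs.
#' @param len length of each random sequence.
#' @return list with `lambda` and `K`.
#' @export
calibrate_karlin <- function(scoring = alignment_scoring(), seed = 1L,
                             n_pairs = 200L, len = 500L) {
  local_seed(seed, {
    scores <- vapply(seq_len(n_pairs), function(i) {
      sw_raw(random_dna(len), random_dna(len), scoring)$score
    }, numeric(1))
    s <- sd(scores)
    if (!is.finite(s) || s <= 0)
      stop("calibration failure: degenerate score distribution; ",
           "use the default constants")
    lambda <- pi / (s * sqrt(6))
    mu <- mean(scores) - 0.5772156649 / lambda
    K <- exp(lambda * mu) / (as.numeric(len) * len)
    list(lambda = lambda, K = K)
  })
}
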