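# Turning raw hits into classified NUMT records: residual-mitochondrial
# filtering, length categories C1-C5, frameshift and premature-stop
# screening (the IPSC diagnosis), and scoring against planted ground truth.

#' Remove residual mitochondrial hits from a hit table
#'
#' Hits that cover the whole query (within 1 bp) and are nearly identical
#' (identity >= 0.99) are either retained mitochondrial sequence that
#' escaped the scaffold screen or NUMTs too recent to affect clustering at
#' a 2% threshold; both are dropped before NUMT counting.
#'
#' @param hits a hit table from [find_hits()].
#' @param query_len length of the query in bp (658 for the barcode).
#' @return the filtered hit table.
#' @export
filter_residual_hits <- function(hits, query_len = 658) {
  q_cov <- hits$q_end - hits$q_start
  drop <- q_cov >= query_len - 1 & hits$identity >= 0.99
  out <- hits[!drop, , drop = FALSE]
  rownames(out) <- NULL
  as_hit_table(out)
}

#' Assign a NUMT length category
#'
#' Five amplicon-relevant categories: C1 100-150 bp, C2 151-300 bp,
#' C3 301-450 bp, C4 451-600 bp, C5 >= 601 bp. Lengths below 100 bp fall
#' outside all categories and return `NA`.
#'
#' @param length numeric vector of NUMT lengths in bp (>= 0).
#' @return character vector of `"C1"`..`"C5"` or `NA`.
#' @examples
#' assign_category(c(99, 150, 151, 754))  # NA "C1" "C2" "C5"
#' @export
assign_category <- function(length) {
  if (any(length < 0)) stop("length must be non-negative")
  out <- rep(NA_character_, length(length))
  out[length >= 100 & length <= 150] <- "C1"
  out[length >= 151 & length <= 300] <- "C2"
  out[length >= 301 & length <= 450] <- "C3"
  out[length >= 451 & length <= 600] <- "C4"
  out[length >= 601] <- "C5"
  out
}

gap_runs <- function(gapped) {
  r <- rle(strsplit(gapped, "", fixed = TRUE)[[1]] == "-")
  r$lengths[r$values]
}

# best-scoring contiguous segment ending at each column (left) and
# starting at each column (right); match +2, mismatch -3, gap column -2
best_segment_scores <- function(q, s) {
  gap <- q == "-" | s == "-"
  colsc <- ifelse(gap, -2, ifelse(q == s, 2, -3))
  n <- length(colsc)
  left <- numeric(n); run <- 0
  for (k in seq_len(n)) { run <- max(0, run) + colsc[k]; left[k] <- run }
  right <- numeric(n); run <- 0
  for (k in rev(seq_len(n))) { run <- max(0, run) + colsc[k]; right[k] <- run }
  list(left = left, right = right)
}

# Frameshift evidence near the homology boundaries. The strict diagnostic
# re-alignment drops a true indel lying within a few bases of the boundary
# (its short flank does not pay for the heavier gap cost there), so gaps
# the sensitive search alignment placed outside the diagnostic core's
# query span are accepted instead — provided a well-scoring segment flanks
# the gap on both sides, which a spurious boundary gap lacks.
end_zone_frameshift <- function(q_gapped, s_gapped, q_start, core_q_span,
                                theta = 10) {
  q <- strsplit(q_gapped, "", fixed = TRUE)[[1]]
  s <- strsplit(s_gapped, "", fixed = TRUE)[[1]]
  gap <- q == "-" | s == "-"
  if (!any(gap)) return(FALSE)
  bs <- best_segment_scores(q, s)
  qpos <- q_start + cumsum(q != "-")  # query coord after each column
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gi <- which(r$values)
  n <- length(gap)
  for (k in gi) {
    if (r$lengths[k] %% 3 == 0) next
    gq <- qpos[starts[k]]
    if (gq >= core_q_span[1] + 3 && gq <= core_q_span[2] - 3) next
    la <- if (starts[k] > 1) bs$left[starts[k] - 1L] else 0
    ra <- if (ends[k] < n) bs$right[ends[k] + 1L] else 0
    if (la >= theta && ra >= theta) return(TRUE)
  }
  FALSE
}

# maximum-scoring contiguous column window (match +2, mismatch -3,
# gap column -2), as (first, last) column indices
max_score_window <- function(q, s) {
  gap <- q == "-" | s == "-"
  sc <- ifelse(gap, -2, ifelse(q == s, 2, -3))
  best <- run <- 0; b1 <- b2 <- r1 <- 0L
  for (k in seq_along(sc)) {
    if (run <= 0) { run <- sc[k]; r1 <- k } else run <- run + sc[k]
    if (run > best) { best <- run; b1 <- r1; b2 <- k }
  }
  if (b1 == 0L) c(1L, length(sc)) else c(b1, b2)
}

# Trim unreliable alignment ends before IPSC diagnosis. A local alignment
# can extend a few columns past the true homology boundary and pick up a
# spurious gap there; such a gap is distinguished from a real indel by the
# weak support outside it: a gap run is dropped (together with everything
# outside it) unless some segment of columns touching it from the outside
# scores at least `theta` (8 = four clean matches). Returns the trimmed
# rows plus the number of query bases trimmed on the left (needed to
# re-anchor the reading frame).
trim_alignment_ends <- function(q_gapped, s_gapped, theta = 8,
                                match = 2, mismatch = -3) {
  q <- strsplit(q_gapped, "", fixed = TRUE)[[1]]
  s <- strsplit(s_gapped, "", fixed = TRUE)[[1]]
  n <- length(q)
  gap <- q == "-" | s == "-"
  col_score <- ifelse(gap, 0, ifelse(q == s, match, mismatch))
  # best-scoring segment ending at k (from the left) / starting at k
  best_seg <- function(scores) {
    out <- numeric(length(scores)); run <- 0
    for (k in seq_along(scores)) {
      run <- max(0, run) + scores[k]
      out[k] <- run
    }
    out
  }
  left_best <- best_seg(col_score)
  right_best <- rev(best_seg(rev(col_score)))
  lo <- 1L; hi <- n
  repeat {
    changed <- FALSE
    # left end
    g <- which(gap[lo:hi])
    if (length(g) > 0) {
      g1 <- lo + g[1] - 1L
      if (g1 == lo || left_best[g1 - 1L] < theta) {
        g_end <- g1
        while (g_end < hi && gap[g_end + 1L]) g_end <- g_end + 1L
        lo <- g_end + 1L
        changed <- TRUE
      }
    }
    # right end
    g <- which(gap[lo:hi])
    if (length(g) > 0) {
      g2 <- lo + g[length(g)] - 1L
      if (g2 == hi || right_best[g2 + 1L] < theta) {
        g_start <- g2
        while (g_start > lo && gap[g_start - 1L]) g_start <- g_start - 1L
        hi <- g_start - 1L
        changed <- TRUE
      }
    }
    if (!changed || lo > hi) break
  }
  if (lo > hi)
    return(list(q = "", s = "", q_trimmed_left = sum(q[gap == FALSE] != "-")))
  q_left <- if (lo > 1) sum(q[1:(lo - 1L)] != "-") else 0L
  list(q = paste(q[lo:hi], collapse = ""),
       s = paste(s[lo:hi], collapse = ""),
       q_trimmed_left = q_left)
}

#' Detect a frameshift indel in a gapped alignment
#'
#' A NUMT is frameshifted when any maximal gap run, in either row, has a
#' length that is not a multiple of three. The rule is applied per gap, so
#' two compensating gaps (e.g. 2 bp + 1 bp) count as frameshifts even
#' though the net frame is restored.
#'
#' @param q_gapped,s_gapped aligned rows of equal length, gaps as `-`.
#' @return logical scalar.
#' @export
detect_frameshift <- function(q_gapped, s_gapped) {
  any(c(gap_runs(q_gapped), gap_runs(s_gapped)) %% 3 != 0)
}

#' Screen an aligned NUMT for a premature stop codon
#'
#' The subject (NUMT) sequence is read in the frame implied by the query:
#' translation starts at the first complete codon given the query phase and
#' proceeds through each gap-free block of the alignment, re-anchoring to
#' the query frame after every gap. Under the invertebrate mitochondrial
#' code only TAA and TAG are stops (AGA/AGG encode serine, TGA tryptophan).
#' A stop in the final translated codon is terminal, not premature.
#'
#' @param q_gapped,s_gapped aligned rows (query / subject), gaps as `-`.
#' @param q_phase codon phase (0-2) of the first aligned query base; for a
#'   hit this is `(frame_offset + q_start) %% 3`.
#' @param code_table genetic-code identifier (default table 5).
#' @param margin integer pair: codons at the (start, end) of the translated
#'   span within which a stop is not called. The default `c(0, 1)` encodes
#'   the definitional rule that a terminal stop codon is not premature.
#' @param anchor optional score threshold: when set, a stop codon is only
#'   called if on each side of it some alignment segment touching the codon
#'   scores at least `anchor` (match +2, mismatch -3, gap column -2). This
#'   suppresses stops read from the few unalignable columns a local
#'   alignment can carry at its ends, where flanking evidence is negative,
#'   while a genuine stop inside or at the edge of the homologous span is
#'   anchored by the homology around it. `NULL` (default) disables the
#'   check.
#' @return logical scalar; `FALSE` with a warning when fewer than two
#'   codons are translatable.
#' @export
detect_premature_stop <- function(q_gapped, s_gapped, q_phase,
                                  code_table = "5", margin = c(0L, 1L),
                                  anchor = NULL) {
  code <- genetic_code(code_table)
  q <- strsplit(q_gapped, "", fixed = TRUE)[[1]]
  s <- strsplit(s_gapped, "", fixed = TRUE)[[1]]
  stopifnot(length(q) == length(s))
  gap <- q == "-" | s == "-"
  # split into maximal gap-free blocks
  blocks <- list()
  i <- 1L; qpos <- 0L  # query offset from alignment start (query bases seen)
  n <- length(q)
  while (i <= n) {
    if (gap[i]) {
      if (q[i] != "-") qpos <- qpos + 1L
      i <- i + 1L
      next
    }
    j <- i
    qa <- qpos
    while (j <= n && !gap[j]) { j <- j + 1L; qpos <- qpos + 1L }
    blocks[[length(blocks) + 1L]] <- list(start = i, end = j - 1L, q_off = qa)
    i <- j
  }
  codons <- character(0)
  col_first <- col_last <- integer(0)
  for (b in blocks) {
    blen <- b$end - b$start + 1L
    phase_at_start <- (q_phase + b$q_off) %% 3
    off <- (3L - phase_at_start) %% 3L
    n_cod <- (blen - off) %/% 3L
    if (n_cod <= 0) next
    sub <- paste(s[(b$start + off):(b$start + off + 3L * n_cod - 1L)],
                 collapse = "")
    codons <- c(codons, substring(sub, 3 * seq_len(n_cod) - 2,
                                  3 * seq_len(n_cod)))
    col_first <- c(col_first, b$start + off + 3L * (seq_len(n_cod) - 1L))
    col_last <- c(col_last, b$start + off + 3L * seq_len(n_cod) - 1L)
  }
  if (length(codons) < 2) {
    warning("fewer than two translatable codons; stop screen undefined")
    return(FALSE)
  }
  is_stop <- !is.na(code[codons]) & code[codons] == "*"
  idx <- which(is_stop)
  idx <- idx[idx > margin[1] & idx <= length(is_stop) - margin[2]]
  if (length(idx) == 0) return(FALSE)
  if (is.null(anchor)) return(TRUE)
  col_score <- ifelse(gap, -2, ifelse(q == s, 2, -3))
  cum <- c(0, cumsum(col_score))          # cum[k+1] = score of columns 1..k
  runmin <- cummin(cum)                   # min over cum[1..k]
  runmax <- rev(cummax(rev(cum)))         # max over cum[k..n+1]
  for (i in idx) {
    # best-scoring segment ending just before / starting just after codon i
    left <- cum[col_first[i]] - runmin[col_first[i]]
    right <- runmax[col_last[i] + 1L] - cum[col_last[i] + 1L]
    if (left >= anchor && right >= anchor) return(TRUE)
  }
  FALSE
}

# Context strings (query orientation) for the diagnostic re-alignment:
# the hit's aligned spans plus up to `flank` bp on each side when the
# query and scaffold sequences are available.
diag_context <- function(hit, query, scaffolds, si, flank) {
  if (is.null(query) || is.null(scaffolds) || is.na(si)) {
    return(list(q = gsub("-", "", hit$q_gapped, fixed = TRUE),
                s = gsub("-", "", hit$s_gapped, fixed = TRUE),
                q_flank = 0L))
  }
  lq <- min(flank, hit$q_start)
  rq <- min(flank, nchar(query) - hit$q_end)
  qc <- seq_slice(query, hit$q_start - lq, hit$q_end + rq)
  scaf <- scaffolds$sequence[si]
  slen <- nchar(scaf)
  if (hit$strand == "+") {
    ls <- min(flank, hit$s_start)
    rs <- min(flank, slen - hit$s_end)
    sc <- seq_slice(scaf, hit$s_start - ls, hit$s_end + rs)
  } else {
    ls <- min(flank, slen - hit$s_end)   # left flank in query orientation
    rs <- min(flank, hit$s_start)
    sc <- revcomp(seq_slice(scaf, hit$s_start - rs, hit$s_end + ls))
  }
  list(q = qc, s = sc, q_flank = lq)
}

# Ungapped end extension of an alignment under an X-drop rule: columns are
# appended while the running score stays within `tol` of its maximum, so a
# diverged NUMT flank (positive score drift) is recovered to the flank
# limit while random background (strongly negative drift) terminates the
# walk within a few bases. Downstream screens treat the extension's
# unalignable tail via their own anchoring rules.
extend_alignment_ends <- function(qc, sc, a, scoring, tol) {
  qv <- strsplit(qc, "", fixed = TRUE)[[1]]
  sv <- strsplit(sc, "", fixed = TRUE)[[1]]
  col_sc <- function(x, y) {
    if (x == "N" || y == "N" || x != y) scoring$mismatch else scoring$match
  }
  # left
  qi <- a$q_start; si <- a$s_start  # 0-based starts
  cum <- 0; best <- 0; nl <- 0L
  while (qi - nl > 0 && si - nl > 0) {
    cum <- cum + col_sc(qv[qi - nl], sv[si - nl])
    if (best - cum > tol) break
    if (cum > best) best <- cum
    nl <- nl + 1L
  }
  # right
  qj <- a$q_end; sj <- a$s_end  # 0-based half-open ends
  cum <- 0; best <- 0; nr <- 0L
  while (qj + nr < length(qv) && sj + nr < length(sv)) {
    cum <- cum + col_sc(qv[qj + nr + 1L], sv[sj + nr + 1L])
    if (best - cum > tol) break
    if (cum > best) best <- cum
    nr <- nr + 1L
  }
  left_q <- if (nl > 0) paste(qv[(qi - nl + 1L):qi], collapse = "") else ""
  left_s <- if (nl > 0) paste(sv[(si - nl + 1L):si], collapse = "") else ""
  right_q <- if (nr > 0) paste(qv[(qj + 1L):(qj + nr)], collapse = "") else ""
  right_s <- if (nr > 0) paste(sv[(sj + 1L):(sj + nr)], collapse = "") else ""
  list(q_gapped = paste0(left_q, a$q_gapped, right_q),
       s_gapped = paste0(left_s, a$s_gapped, right_s),
       q_start = a$q_start - nl)
}

#' Classify filtered hits into NUMT records
#'
#' Populates, per hit: the subject-side length (insertion-inclusive, as a
#' BLAST hit length reads), the C1-C5 length category, percent divergence
#' over non-gap non-N columns, the frameshift and premature-stop flags,
#' their union (`has_ipsc`), and the C5* flag (651-661 bp span, no IPSC,
#' divergence > 2%) marking NUMTs able to masquerade as full barcodes.
#'
#' Diagnosis is performed on a stricter re-alignment of the hit: the search
#' scoring (+2/-3, gap 5+2k) is tuned for sensitivity and will occasionally
#' explain runs of mismatches in a diverged NUMT with pairs of compensating
#' micro-gaps; re-aligning with heavier gap costs (`diag_scoring`, default
#' gap 12+3k) removes those artifacts while true indels — whose omission
#' would misalign everything downstream — are unaffected. When the query
#' and scaffold sequences are supplied, the re-alignment's ends are then
#' extended without gaps into the flanks while the running score stays
#' within `flank_tol` of its maximum, so diagnostic features in the last
#' few bases — which optimal local alignment trims away — are still
#' screened; random background beyond a NUMT boundary fails the tolerance
#' immediately. Weakly supported terminal gaps are trimmed before
#' screening. Two flank-evidence rules then police the boundary region,
#' where a local alignment cannot fully separate homology from background:
#' a frameshift gap placed by the sensitive search alignment outside the
#' re-alignment's span is accepted only when well-scoring segments flank
#' it on both sides, and a stop codon near the span ends requires stronger
#' flanking evidence than one in the interior (see
#' [detect_premature_stop()]'s `anchor`).
#'
#' @param hits a filtered hit table (after [filter_residual_hits()]).
#' @param query the query sequence the hits were found with (enables end
#'   extension).
#' @param scaffolds the scanned [scaffold_set()] (enables end extension).
#' @param frame_offset codon phase of the first query base (0-2).
#' @param code_table genetic-code identifier.
#' @param diag_scoring an [alignment_scoring()] used for the diagnostic
#'   re-alignment.
#' @param flank maximum end-extension length in bp.
#' @param flank_tol X-drop tolerance for end extension.
#' @return data.frame of class `numt_records`: the hit columns plus
#'   `length`, `category`, `divergence`, `has_frameshift`,
#'   `has_premature_stop`, `has_ipsc`, `is_c5_star`.
#' @export
classify_numts <- function(hits, query = NULL, scaffolds = NULL,
                           frame_offset = 0L, code_table = "5",
                           diag_scoring = alignment_scoring(gap_open = 12,
                                                            gap_extend = 3),
                           flank = 15L, flank_tol = 9) {
  n <- nrow(hits)
  length_bp <- hits$s_end - hits$s_start  # overwritten per record below
  divergence <- numeric(n)
  has_fs <- logical(n)
  has_stop <- logical(n)
  scaf_idx <- if (!is.null(scaffolds))
    match(hits$scaffold_id, scaffolds$id) else rep(NA_integer_, n)
  for (i in seq_len(n)) {
    q <- strsplit(hits$q_gapped[i], "", fixed = TRUE)[[1]]
    s <- strsplit(hits$s_gapped[i], "", fixed = TRUE)[[1]]
    # divergence over the maximum-scoring core of the alignment, so the
    # few unalignable columns a hit may carry at its span boundaries do
    # not bias the estimate
    core_win <- max_score_window(q, s)
    ok <- q != "-" & s != "-" & q != "N" & s != "N"
    ok[seq_along(ok) < core_win[1] | seq_along(ok) > core_win[2]] <- FALSE
    divergence[i] <- if (any(ok)) 100 * mean(q[ok] != s[ok]) else NA_real_
    # length: subject-side span of the same core (as a BLAST hit length
    # reads), not the extended boundary estimate in s_start/s_end
    length_bp[i] <- sum(s[core_win[1]:core_win[2]] != "-")

    # context strings with flanks, in query orientation
    ctx <- diag_context(hits[i, ], query, scaffolds, scaf_idx[i], flank)
    da <- sw_raw(ctx$q, ctx$s, diag_scoring)
    if (da$score <= 0) next
    ext <- extend_alignment_ends(ctx$q, ctx$s, da, diag_scoring, flank_tol)
    core <- trim_alignment_ends(ext$q_gapped, ext$s_gapped, theta = 8)
    if (nchar(core$q) == 0) next
    q_start_global <- hits$q_start[i] - ctx$q_flank + ext$q_start +
      core$q_trimmed_left
    core_q_span <- c(q_start_global,
                     q_start_global + sum(strsplit(core$q, "",
                                                   fixed = TRUE)[[1]] != "-"))
    has_fs[i] <- detect_frameshift(core$q, core$s) ||
      end_zone_frameshift(hits$q_gapped[i], hits$s_gapped[i],
                          hits$q_start[i], core_q_span)
    q_phase <- ((frame_offset + q_start_global) %% 3 + 3) %% 3
    has_stop[i] <-
      detect_premature_stop(core$q, core$s, q_phase, code_table,
                            margin = c(3L, 3L), anchor = 2) ||
      detect_premature_stop(core$q, core$s, q_phase, code_table,
                            margin = c(0L, 1L), anchor = 8)
  }
  rec <- as.data.frame(hits)
  rec$length <- length_bp
  rec$category <- assign_category(length_bp)
  rec$divergence <- divergence
  rec$has_frameshift <- has_fs
  rec$has_premature_stop <- has_stop
  rec$has_ipsc <- has_fs | has_stop
  rec$is_c5_star <- length_bp >= 651 & length_bp <= 661 &
    !rec$has_ipsc & divergence > 2.0
  structure(rec, class = c("numt_records", "data.frame"))
}

#' @export
print.numt_records <- function(x, ...) {
  cat(sprintf("numt_records: %d NUMT(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    tab <- table(factor(x$category, levels = paste0("C", 1:5)))
    cat("  categories:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = " "), "\n")
    cat(sprintf("  IPSC: %d/%d   C5*: %d   mean divergence: %.1f%%\n",
                sum(x$has_ipsc), nrow(x), sum(x$is_c5_star),
                mean(x$divergence, na.rm = TRUE)))
  }
  invisible(x)
}

#' Score classified records against planted ground truth
#'
#' A record matches a truth entry when both lie on the same scaffold and
#' their intervals reciprocally overlap by at least `min_overlap`; matching
#' is greedy by decreasing overlap, one-to-one. Divergence error is the
#' absolute difference between detected percent divergence and the planted
#' substituted-site fraction; the IPSC confusion table compares planted
#' frameshift/stop status with the detected `has_ipsc` flag.
#'
#' @param records a [classify_numts()] table.
#' @param truth a truth data.frame from [plant_numts()].
#' @param min_overlap reciprocal-overlap fraction.
#' @return list of class `recovery_metrics`: `recall`, `precision`,
#'   `divergence_mae`, `ipsc` (TP/FP/FN/TN), `matches` (index pairs).
#' @export
evaluate_against_truth <- function(records, truth, min_overlap = 0.5) {
  nr <- nrow(records); nt <- nrow(truth)
  pairs <- list()
  if (nr > 0 && nt > 0) {
    for (i in seq_len(nr)) {
      for (j in seq_len(nt)) {
        if (records$scaffold_id[i] != truth$scaffold_id[j]) next
        ov <- min(records$s_end[i], truth$insert_end[j]) -
          max(records$s_start[i], truth$insert_start[j])
        if (ov <= 0) next
        if (ov >= min_overlap * (records$s_end[i] - records$s_start[i]) &&
            ov >= min_overlap * (truth$insert_end[j] - truth$insert_start[j]))
          pairs[[length(pairs) + 1L]] <- c(i, j, ov)
      }
    }
  }
  used_r <- logical(nr); used_t <- logical(nt)
  matched <- list()
  if (length(pairs) > 0) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(-pm[, 3]), , drop = FALSE]
    for (k in seq_len(nrow(pm))) {
      i <- pm[k, 1]; j <- pm[k, 2]
      if (used_r[i] || used_t[j]) next
      used_r[i] <- TRUE; used_t[j] <- TRUE
      matched[[length(matched) + 1L]] <- c(record = i, truth = j)
    }
  }
  m <- if (length(matched)) do.call(rbind, matched) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("record", "truth")))
  mae <- mae_gapfree <- NA_real_
  ipsc <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  if (nrow(m) > 0) {
    dv_det <- records$divergence[m[, 1]]
    dv_true <- 100 * truth$divergence[m[, 2]]
    mae <- mean(abs(dv_det - dv_true))
    gf <- truth$n_indels[m[, 2]] == 0
    if (any(gf)) mae_gapfree <- mean(abs(dv_det - dv_true)[gf])
    det <- records$has_ipsc[m[, 1]]
    pl <- truth$has_frameshift[m[, 2]] | truth$has_planted_stop[m[, 2]]
    ipsc <- c(TP = sum(det & pl), FP = sum(det & !pl),
              FN = sum(!det & pl), TN = sum(!det & !pl))
  }
  structure(list(
    recall = if (nt > 0) sum(used_t) / nt else NA_real_,
    precision = if (nr > 0) sum(used_r) / nr else NA_real_,
    divergence_mae = mae, divergence_mae_gapfree = mae_gapfree,
    ipsc = ipsc, matches = m),
    class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("recovery_metrics: recall %.3f, precision %.3f, divergence MAE %.2f pp\n",
              x$recall, x$precision, x$divergence_mae))
  cat(sprintf("  IPSC confusion: TP=%d FP=%d FN=%d TN=%d\n",
              x$ipsc["TP"], x$ipsc["FP"], x$ipsc["FN"], x$ipsc["TN"]))
  invisible(x)
}
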