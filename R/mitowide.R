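# Mitogenome-wide NUMT counting: 658 bp windows over the concatenated
# annotated gene regions, and the COI-versus-genome-wide log2 regression.

#' Partition a mitogenome's gene regions into barcode-sized windows
#'
#' The 13 protein-coding genes and two rRNAs are concatenated in genome
#' order and cut into non-overlapping windows of `window` bp; the trailing
#' remainder is dropped. The default mitogenome yields 15-22 windows.
#'
#' @param mitogenome a [generate_mitogenome()] object.
#' @param window window size in bp (window and slide are both 658).
#' @return character vector of window sequences, with a `windows`
#'   data.frame attribute giving each window's interval on the
#'   concatenated gene sequence. Empty (with a warning) when the
#'   concatenated genes are shorter than one window.
#' @export
partition_windows <- function(mitogenome, window = 658L) {
  genes <- mitogenome$genes[order(mitogenome$genes$start), ]
  concat <- paste(vapply(seq_len(nrow(genes)), function(i)
    seq_slice(mitogenome$sequence, genes$start[i], genes$end[i]),
    character(1)), collapse = "")
  n <- nchar(concat) %/% window
  if (n == 0) {
    warning("concatenated gene regions shorter than one window")
    return(character(0))
  }
  starts <- (seq_len(n) - 1L) * window
  out <- vapply(starts, function(st) seq_slice(concat, st, st + window),
                character(1))
  names(out) <- sprintf("w%d", seq_len(n))
  attr(out, "windows") <- data.frame(window = names(out), start = starts,
                                     end = starts + window,
                                     stringsAsFactors = FALSE)
  out
}

#' Count NUMTs per mitogenome window
#'
#' Runs the hit scan and residual filter once per window sequence (each
#' window acting as the query) and once for the 658 bp COI barcode. A NUMT
#' spanning two windows is counted in both, matching a per-fragment search
#' design.
#'
#' @param assembly a mito-screened [scaffold_set()].
#' @param mitogenome a [generate_mitogenome()] object.
#' @param windows output of [partition_windows()]; computed when `NULL`.
#' @param scoring an [alignment_scoring()].
#' @param ... passed to [find_hits()] (thresholds).
#' @return list of class `window_counts`: `counts` (named per-window),
#'   `mean_count`, `coi_count`.
#' @export
windowed_counts <- function(assembly, mitogenome, windows = NULL,
                            scoring = alignment_scoring(), ...) {
  if (is.null(windows)) windows <- partition_windows(mitogenome)
  counts <- vapply(windows, function(w) {
    h <- find_hits(w, assembly, scoring, query_id = "window", ...)
    nrow(filter_residual_hits(h, query_len = nchar(w)))
  }, numeric(1))
  bc <- mito_barcode(mitogenome)
  coi <- nrow(filter_residual_hits(
    find_hits(bc$sequence, assembly, scoring, query_id = "coi", ...),
    query_len = nchar(bc$sequence)))
  structure(list(counts = counts,
                 mean_count = if (length(counts)) mean(counts) else NA_real_,
                 coi_count = coi),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("window_counts: %d windows, mean %.2f, COI barcode %d\n",
              length(x$counts), x$mean_count, x$coi_count))
  invisible(x)
}

#' Simulate a multi-species windowed NUMT survey
#'
#' For each synthetic species: generate a mitogenome, plant NUMTs with
#' source intervals sampled uniformly over the whole mitogenome (the
#' null hypothesis of equal integration susceptibility), count NUMTs per
#' 658 bp gene-region window and for the COI barcode query. Per-species
#' NUMT totals are drawn log-uniformly over `n_range`, mimicking the
#' orders-of-magnitude spread of real counts.
#'
#' @param n_species number of synthetic species.
#' @param seed integer master seed.
#' @param n_range range of per-species planted NUMT counts.
#' @param n_scaffolds,scaffold_length background assembly per species.
#' @param d_range,length_range planting parameters, see [plant_numts()].
#' @return data.frame with `species`, `n_planted`, `coi_count`,
#'   `window_mean`.
#' @export
survey_numt_counts <- function(n_species = 100L, seed = 1L,
                               n_range = c(4, 256),
                               n_scaffolds = 4L, scaffold_length = 60000L,
                               d_range = c(0.03, 0.30),
                               length_range = c(100, 1600)) {
  out <- data.frame(species = seq_len(n_species), n_planted = NA_integer_,
                    coi_count = NA_real_, window_mean = NA_real_)
  for (i in seq_len(n_species)) {
    sp_seed <- derive_seed(seed, i)
    mg <- generate_mitogenome(sp_seed)
    asm <- make_background_assembly(n_scaffolds, scaffold_length,
                                    seed = derive_seed(sp_seed, 1))
    n <- local_seed(derive_seed(sp_seed, 2),
                    round(2^runif(1, log2(n_range[1]), log2(n_range[2]))))
    pl <- plant_numts(asm, mg, n, source = "mitogenome",
                      length_range = length_range, d_range = d_range,
                      seed = derive_seed(sp_seed, 3))
    wc <- windowed_counts(pl$assembly, mg)
    out$n_planted[i] <- n
    out$coi_count[i] <- wc$coi_count
    out$window_mean[i] <- wc$mean_count
  }
  out
}

#' log2-log2 regression of window-mean NUMT counts on COI counts
#'
#' Ordinary least squares of `log2(y)` on `log2(x)` after dropping pairs
#' where either value is zero (species without NUMTs carry no information
#' about proportionality). A slope near 1 indicates the barcode region is
#' integrated at the same rate as the rest of the mitogenome.
#'
#' @param x per-species COI NUMT counts.
#' @param y per-species mean window NUMT counts.
#' @param drop_zero drop pairs containing a zero.
#' @return list with `slope`, `intercept`, `r2`, `n`.
#' @export
log2_regression <- function(x, y, drop_zero = TRUE) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (drop_zero) keep <- keep & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("fewer than 3 usable pairs for the log2 regression")
  fit <- lm(log2(y) ~ log2(x))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = summary(fit)$r.squared, n = length(x))
}
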