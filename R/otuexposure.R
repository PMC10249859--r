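# OTU clustering of NUMT/mtCOI sequence sets and the exposure arithmetic:
# how many NUMTs an amplicon protocol can recover, and how much they
# inflate apparent species richness.

category_bounds <- list(C1 = c(100, 150), C2 = c(151, 300), C3 = c(301, 450),
                        C4 = c(451, 600), C5 = c(601, 661))

#' Exposure of a NUMT length category to an amplicon
#'
#' The fraction of a category's NUMTs expected to contain a primer-bound
#' amplicon is its mean length over the 658 bp barcode length; category
#' means are interval midpoints (C5 uses 601-661). Values are rounded to
#' two decimals, the precision the model is used at.
#'
#' @param lo,hi category bounds in bp.
#' @param barcode_len barcode length in bp.
#' @return exposure fraction, rounded to 2 decimals.
#' @examples
#' category_exposure(301, 450)  # 0.57
#' @export
category_exposure <- function(lo, hi, barcode_len = 658) {
  stopifnot(lo > 0, lo <= hi, hi <= 1000)
  round(((lo + hi) / 2) / barcode_len, 2)
}

default_exposures <- function(barcode_len = 658) {
  vapply(category_bounds, function(b) category_exposure(b[1], b[2], barcode_len),
         numeric(1))
}

#' Amplicon protocol specifications
#'
#' Built-in protocols: `"full"` (one 658 bp amplicon; only C5* NUMTs are
#' exposed, at exposure 1), `"dual"` (two amplicons of 307/407 bp spanning
#' the barcode; C3-C5 exposed), `"five"` (five 100-150 bp amplicons;
#' C1-C5 exposed), `"metabarcoding"` (one 300-450 bp amplicon; C3-C5) and
#' `"edna"` (one 100-150 bp amplicon; C1-C5).
#'
#' @param name protocol name.
#' @return list of class `protocol_spec` with `name`, `n_amplicons`,
#'   `amplicon_length` (bp range), `exposed` (category names), `exposure`
#'   (named per-category fractions; `NULL` means the C5*-only rule).
#' @export
protocol_spec <- function(name = c("full", "dual", "five", "metabarcoding",
                                   "edna")) {
  name <- match.arg(name)
  E <- default_exposures()
  spec <- switch(name,
    full = list(n_amplicons = 1L, amplicon_length = c(651, 661),
                exposed = "C5star", exposure = c(C5star = 1)),
    dual = list(n_amplicons = 2L, amplicon_length = c(307, 407),
                exposed = c("C3", "C4", "C5"), exposure = E[c("C3", "C4", "C5")]),
    five = list(n_amplicons = 5L, amplicon_length = c(100, 150),
                exposed = names(E), exposure = E),
    metabarcoding = list(n_amplicons = 1L, amplicon_length = c(300, 450),
                         exposed = c("C3", "C4", "C5"),
                         exposure = E[c("C3", "C4", "C5")]),
    edna = list(n_amplicons = 1L, amplicon_length = c(100, 150),
                exposed = names(E), exposure = E))
  structure(c(list(name = name), spec), class = "protocol_spec")
}

#' Amplifiable NUMT count and per-species exposure under a protocol
#'
#' `amplifiable = sum over exposed categories of count * exposure`; for the
#' full-barcode protocol the exposed set is the C5* count at exposure 1.
#' `per_species = amplifiable / n_species * n_amplicons`.
#'
#' Pass `exposure` to override the midpoint exposures with empirical
#' category means (`mean_length / 658`).
#'
#' @param category_counts named counts (`C1`..`C5`, and/or `C5star`).
#' @param protocol a [protocol_spec()] or protocol name.
#' @param n_species number of species surveyed.
#' @param exposure optional named override of per-category exposures.
#' @return list with `amplifiable` and `per_species`.
#' @examples
#' protocol_exposure(c(C5star = 226), "full", 668)$per_species  # 0.338...
#' @export
protocol_exposure <- function(category_counts, protocol, n_species,
                              exposure = NULL) {
  if (is.character(protocol)) protocol <- protocol_spec(protocol)
  stopifnot(n_species > 0, all(category_counts >= 0))
  E <- protocol$exposure
  if (!is.null(exposure)) E[names(exposure)] <- exposure
  cats <- intersect(names(E), names(category_counts))
  amplifiable <- sum(unlist(category_counts[cats]) * E[cats])
  list(amplifiable = amplifiable,
       per_species = amplifiable / n_species * protocol$n_amplicons)
}

#' Amplifiable NUMTs as a percentage of the species count
#'
#' @param amplifiable_count amplifiable NUMT count (e.g. a protocol total).
#' @param n_species number of species surveyed (> 0).
#' @return integer percent, rounded to the nearest unit.
#' @examples
#' per_species_percent(226, 668)  # 34
#' @export
per_species_percent <- function(amplifiable_count, n_species) {
  stopifnot(amplifiable_count >= 0, n_species > 0)
  as.integer(round(100 * amplifiable_count / n_species))
}

#' Pairwise p-distance matrix of an aligned sequence set
#'
#' `d(i, j)` is the proportion of differing sites over columns where
#' neither sequence has a gap or N (pairwise deletion).
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  mat <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  d <- ape::dist.dna(ape::as.DNAbin(mat), model = "raw",
                     pairwise.deletion = TRUE, as.matrix = TRUE)
  if (any(!is.finite(d)))
    stop("undefined distance: a sequence pair shares no comparable columns")
  d
}

#' Single-linkage OTU clustering at a distance threshold
#'
#' Clusters are the connected components of the graph joining pairs with
#' distance <= `threshold` (transitive chaining, as in single-linkage
#' clustering cut at the threshold). This is the package's documented
#' stand-in for BOLD's Refined Single Linkage (RESL) algorithm.
#'
#' @param d symmetric distance matrix (e.g. [pdistance_matrix()]).
#' @param threshold p-distance threshold (default 0.02, the barcoding
#'   convention).
#' @return list of class `otu_partition`: `clusters` (list of member-id
#'   character vectors, ordered by smallest member), `membership` (named
#'   integer vector), `n_otus`, `threshold`.
#' @export
single_linkage_otus <- function(d, threshold = 0.02) {
  d <- as.matrix(d)
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_len(n))
  if (n == 1) {
    memb <- stats::setNames(1L, ids)
  } else {
    hc <- hclust(as.dist(d), method = "single")
    memb <- cutree(hc, h = threshold)
    names(memb) <- ids
  }
  first <- tapply(seq_len(n), memb, min)
  relabel <- rank(first)  # order clusters by smallest member index
  memb <- stats::setNames(as.integer(relabel[as.character(memb)]), ids)
  clusters <- lapply(sort(unique(memb)), function(k) ids[memb == k])
  structure(list(clusters = clusters, membership = memb,
                 n_otus = length(clusters), threshold = threshold),
            class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  cat(sprintf("otu_partition: %d sequence(s) in %d OTU(s) at %.1f%% threshold\n",
              length(x$membership), x$n_otus, 100 * x$threshold))
  invisible(x)
}

#' OTU conversion percentage
#'
#' The OTU count as a percentage of the input sequence count, rounded to
#' the nearest integer.
#'
#' @param n_otus,n_seqs counts with `0 < n_otus <= n_seqs`.
#' @return integer percent.
#' @examples
#' conversion_percentage(632, 668)  # 95
#' @export
conversion_percentage <- function(n_otus, n_seqs) {
  if (n_otus > n_seqs) stop("n_otus cannot exceed n_seqs")
  stopifnot(n_otus > 0)
  as.integer(round(100 * n_otus / n_seqs))
}

#' Species-richness inflation percentage
#'
#' Percentage increase of the OTU count when NUMT-derived OTUs are added to
#' the mitochondrial OTUs: `100 * ((numt_otus + mt_otus) / mt_otus - 1)`,
#' rounded to the nearest integer.
#'
#' @param numt_otus NUMT-derived OTU count (>= 0).
#' @param mt_otus mitochondrial OTU count (> 0).
#' @return integer percent.
#' @examples
#' inflation_percent(139, 632)  # 22
#' @export
inflation_percent <- function(numt_otus, mt_otus) {
  if (mt_otus <= 0) stop("mt_otus must be positive")
  stopifnot(numt_otus >= 0)
  as.integer(round(100 * ((numt_otus + mt_otus) / mt_otus - 1)))
}

#' Relative mtDNA:NUMT template copy number entering PCR
#'
#' With a nuclear genome `genome_size_ratio` times larger than the
#' mitogenome, a mitochondrial mass fraction `mt_mass_fraction` in the
#' extract, and `numt_copies_per_genome` copies of a NUMT per nuclear
#' genome, mitochondrial template outnumbers the NUMT by
#' `genome_size_ratio * mt_mass_fraction / numt_copies_per_genome`.
#'
#' @param genome_size_ratio nuclear:mitochondrial genome size ratio.
#' @param mt_mass_fraction mitochondrial fraction of extract DNA (>= 0).
#' @param numt_copies_per_genome NUMT copies per nuclear genome (> 0).
#' @return numeric ratio.
#' @examples
#' pcr_copy_ratio(60000, 0.005, 2)  # 150
#' @export
pcr_copy_ratio <- function(genome_size_ratio, mt_mass_fraction,
                           numt_copies_per_genome) {
  if (numt_copies_per_genome == 0)
    stop("numt_copies_per_genome must be positive")
  stopifnot(genome_size_ratio > 0, mt_mass_fraction >= 0,
            numt_copies_per_genome > 0)
  genome_size_ratio * mt_mass_fraction / numt_copies_per_genome
}

#' mtDNA:NUMT ratio after differential PCR amplification
#'
#' Starting from an initial mitochondrial template advantage, a NUMT whose
#' per-cycle amplification factor is `per_cycle_factor_ratio` times the
#' mitochondrial one erodes the advantage geometrically:
#' `final = initial * per_cycle_factor_ratio^(-cycles)`. A result below 1
#' means the NUMT dominates the final amplicon pool.
#'
#' @param initial_mt_advantage initial mtDNA:NUMT copy ratio (> 0).
#' @param per_cycle_factor_ratio NUMT:mtDNA per-cycle amplification-factor
#'   ratio (> 0; 1.2 means the NUMT amplifies 20% faster).
#' @param cycles number of PCR cycles (>= 0).
#' @return final mtDNA:NUMT ratio.
#' @examples
#' pcr_trajectory(150, 1.2, 35)  # ~0.254, the NUMT dominates
#' @export
pcr_trajectory <- function(initial_mt_advantage, per_cycle_factor_ratio,
                           cycles) {
  stopifnot(initial_mt_advantage > 0, per_cycle_factor_ratio > 0,
            cycles >= 0)
  initial_mt_advantage * per_cycle_factor_ratio^(-cycles)
}
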