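# Screening assemblies for residual mitochondrial sequence before NUMT
# scanning, and validating candidate mitogenomes by gene content and order.

#' Drop scaffolds labelled as mitochondrial
#'
#' Removes every scaffold whose FASTA description matches the
#' mitochondrial-label rule (case-insensitive "mitochondri"), regardless of
#' length.
#'
#' @param assembly a [scaffold_set()].
#' @return list with `assembly` (filtered) and `removed` (character vector
#'   of removed scaffold ids).
#' @export
drop_labelled_scaffolds <- function(assembly) {
  drop <- is_mito_labelled(assembly$description)
  list(assembly = scaffold_set(assembly$id[!drop], assembly$sequence[!drop],
                               assembly$description[!drop]),
       removed = assembly$id[drop])
}

#' Detect unannotated mitogenome scaffolds
#'
#' A scaffold is a mitogenome candidate when the union of its alignments to
#' the reference mitogenome covers at least `min_cov` of the reference and
#' the scaffold is no longer than `max_len`. Longer scaffolds with high
#' coverage are never auto-classified (a whole-mitogenome insertion into a
#' chromosome is indistinguishable from an expanded mitogenome); they are
#' reported for review instead. The reference is scanned in ~1.5 kb chunks
#' so the aligner sees queries of ordinary size.
#'
#' @param assembly a [scaffold_set()].
#' @param mitogenome a [generate_mitogenome()] object, or any list with a
#'   `sequence` element.
#' @param min_cov minimum alignable fraction of the reference.
#' @param min_ident identity threshold passed to the aligner.
#' @param max_len maximum scaffold length (bp) for auto-classification.
#' @param scoring an [alignment_scoring()].
#' @return list with `candidates` (scaffold ids) and `flagged` (ids above
#'   `max_len` that met the coverage rule).
#' @export
detect_mito_scaffolds <- function(assembly, mitogenome, min_cov = 0.80,
                                  min_ident = 0.95, max_len = 20000,
                                  scoring = alignment_scoring()) {
  mseq <- mitogenome$sequence
  mlen <- nchar(mseq)
  chunk <- 1500L
  starts <- seq(0L, mlen - 1L, by = chunk)
  candidates <- character(0)
  flagged <- character(0)
  for (si in seq_len(nrow(assembly))) {
    scaf <- scaffold_set(assembly$id[si], assembly$sequence[si],
                         assembly$description[si])
    covered <- 0L
    for (st in starts) {
      en <- min(mlen, st + chunk)
      if (en - st < 200) next
      h <- find_hits(seq_slice(mseq, st, en), scaf, scoring,
                     min_len = 100, min_identity = min_ident,
                     max_evalue = 1e-4)
      if (nrow(h) == 0) next
      # union of covered reference positions within this chunk
      iv <- cbind(h$q_start, h$q_end)
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      last <- -1
      for (k in seq_len(nrow(iv))) {
        a <- max(iv[k, 1], last); b <- iv[k, 2]
        if (b > a) { covered <- covered + (b - a); last <- b }
        else last <- max(last, b)
      }
    }
    if (covered / mlen >= min_cov) {
      if (nchar(assembly$sequence[si]) <= max_len)
        candidates <- c(candidates, assembly$id[si])
      else
        flagged <- c(flagged, assembly$id[si])
    }
  }
  list(candidates = candidates, flagged = flagged)
}

#' Screen an assembly for mitochondrial scaffolds
#'
#' Convenience wrapper: drops labelled scaffolds, then removes detected
#' unannotated mitogenome candidates.
#'
#' @inheritParams detect_mito_scaffolds
#' @return list with `assembly` (cleaned), `removed_labelled`,
#'   `removed_detected`, `flagged`.
#' @export
mito_screen <- function(assembly, mitogenome, min_cov = 0.80,
                        min_ident = 0.95, max_len = 20000,
                        scoring = alignment_scoring()) {
  lab <- drop_labelled_scaffolds(assembly)
  det <- detect_mito_scaffolds(lab$assembly, mitogenome, min_cov, min_ident,
                               max_len, scoring)
  keep <- !(lab$assembly$id %in% det$candidates)
  list(assembly = scaffold_set(lab$assembly$id[keep],
                               lab$assembly$sequence[keep],
                               lab$assembly$description[keep]),
       removed_labelled = lab$removed,
       removed_detected = det$candidates,
       flagged = det$flagged)
}

#' Validate a candidate mitogenome annotation
#'
#' `TRUE` when the 13 canonical protein-coding genes are each present
#' exactly once and their circular order matches the canonical insect gene
#' order under some rotation, with the strand pattern matching under the
#' same rotation. Reflections (reversed order) do not validate. Unknown
#' gene names raise an error rather than returning `FALSE`.
#'
#' @param gene_table data.frame with columns `name`, `start`, `end`,
#'   `strand`; rRNA rows are ignored.
#' @return logical scalar.
#' @export
validate_mitogenome <- function(gene_table) {
  canon <- mito_gene_skeleton(1536L)
  canon <- canon[canon$type == "pcg", ]
  pcg <- gene_table[!gene_table$name %in% c("rrnL", "rrnS"), , drop = FALSE]
  unknown <- setdiff(pcg$name, canon$name)
  if (length(unknown) > 0)
    stop("unknown gene name(s): ", paste(unknown, collapse = ", "))
  if (nrow(pcg) != 13 || anyDuplicated(pcg$name) ||
      !setequal(pcg$name, canon$name))
    return(FALSE)
  pcg <- pcg[order(pcg$start), ]
  n <- 13L
  for (r in 0:(n - 1L)) {
    idx <- ((seq_len(n) - 1L + r) %% n) + 1L
    if (identical(pcg$name[idx], canon$name) &&
        identical(pcg$strand[idx], canon$strand))
      return(TRUE)
  }
  FALSE
}
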