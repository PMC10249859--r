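# Synthetic mitogenomes, nuclear assemblies and planted NUMTs with full
# ground truth. The generator is the package's substitute for downloading
# real assemblies: every downstream stage is scored against the truth
# tables produced here.

# Canonical insect mitochondrial gene order (13 protein-coding genes plus
# the two rRNAs; tRNAs are not modelled). Strands follow the usual
# majority/minority split.
mito_gene_skeleton <- function(coi_length) {
  data.frame(
    name   = c("ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3", "ND3",
               "ND5", "ND4", "ND4L", "ND6", "CYTB", "ND1", "rrnL", "rrnS"),
    length = c(1023L, as.integer(coi_length), 687L, 159L, 675L, 789L, 354L,
               1719L, 1341L, 291L, 525L, 1137L, 948L, 1325L, 789L),
    strand = c("+", "+", "+", "+", "+", "+", "+",
               "-", "-", "-", "+", "+", "-", "-", "-"),
    type   = c(rep("pcg", 13), "rrna", "rrna"),
    stringsAsFactors = FALSE)
}

#' The 13 canonical protein-coding mitochondrial gene names, in order
#' @return character vector of length 13.
#' @export
canonical_pcg_order <- function() mito_gene_skeleton(1536L)$name[1:13]

code_table_cache <- new.env(parent = emptyenv())

genetic_code <- function(code_table = "5") {
  key <- as.character(code_table)
  if (is.null(code_table_cache[[key]]))
    code_table_cache[[key]] <- Biostrings::getGeneticCode(key)
  code_table_cache[[key]]
}

#' Translate a DNA string
#'
#' @param seq DNA string, length a multiple of 3 not required (a trailing
#'   partial codon is dropped).
#' @param code_table NCBI genetic-code identifier; `"5"` is the invertebrate
#'   mitochondrial code, under which TAA/TAG are the only stop codons.
#' @return amino-acid string, stops as `*`.
#' @export
translate_dna <- function(seq, code_table = "5") {
  code <- genetic_code(code_table)
  n <- nchar(seq) %/% 3
  if (n == 0) return("")
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Generate a synthetic annotated mitogenome
#'
#' Emits a linear sequence carrying the 13 protein-coding genes and two
#' rRNAs in the canonical insect order. Protein-coding genes are built from
#' codons drawn uniformly from the sense codons of the configured genetic
#' code, so no gene contains an in-frame stop; rRNA and intergenic tracts
#' are i.i.d. uniform A/C/G/T. The 658 bp barcode interval is placed near
#' the 5' end of COI with a configurable codon phase.
#'
#' @param seed integer RNG seed; identical calls are byte-identical.
#' @param length total genome length in bp (12,000-20,000).
#' @param coi_length COI gene length in bp, a multiple of 3, >= 900.
#' @param frame_offset codon phase (0-2) of the first barcode base.
#' @param code_table genetic-code identifier (default invertebrate
#'   mitochondrial, table 5).
#' @return an object of class `mitogenome`: list with `sequence`, `genes`
#'   (name/start/end/strand/type, 0-based half-open), `coi_interval`,
#'   `barcode_interval`, `frame_offset`, `code_table`.
#' @examples
#' mg <- generate_mitogenome(seed = 1)
#' mg$barcode_interval[2] - mg$barcode_interval[1]  # 658
#' @export
generate_mitogenome <- function(seed, length = 15500L, coi_length = 1536L,
                                frame_offset = 1L, code_table = "5") {
  stopifnot(length >= 12000, length <= 20000,
            coi_length %% 3 == 0, coi_length >= 900,
            frame_offset %in% 0:2)
  skel <- mito_gene_skeleton(coi_length)
  genes_total <- sum(skel$length)
  n_gap <- nrow(skel) + 1L
  if (length < genes_total + n_gap)
    stop(sprintf("length %d too small to host all genes (need >= %d)",
                 length, genes_total + n_gap))
  local_seed(seed, {
    gaps <- as.vector(stats::rmultinom(1, length - genes_total,
                                       rep(1 / n_gap, n_gap)))
    code <- genetic_code(code_table)
    sense <- names(code)[code != "*"]
    pieces <- character(0)
    pos <- 0L
    starts <- ends <- integer(nrow(skel))
    for (i in seq_len(nrow(skel))) {
      gap <- random_dna(gaps[i])
      pos <- pos + gaps[i]
      starts[i] <- pos
      if (skel$type[i] == "pcg") {
        coding <- paste(sample(sense, skel$length[i] / 3, replace = TRUE),
                        collapse = "")
        gseq <- if (skel$strand[i] == "-") revcomp(coding) else coding
      } else {
        gseq <- random_dna(skel$length[i])
      }
      pos <- pos + skel$length[i]
      ends[i] <- pos
      pieces <- c(pieces, gap, gseq)
    }
    pieces <- c(pieces, random_dna(gaps[n_gap]))
    sequence <- paste(pieces, collapse = "")
    genes <- data.frame(name = skel$name, start = starts, end = ends,
                        strand = skel$strand, type = skel$type,
                        stringsAsFactors = FALSE)
    coi <- c(genes$start[genes$name == "COX1"], genes$end[genes$name == "COX1"])
    bstart <- coi[1] + 21L + frame_offset
    structure(list(sequence = sequence, genes = genes,
                   coi_interval = coi,
                   barcode_interval = c(bstart, bstart + 658L),
                   frame_offset = as.integer(frame_offset),
                   code_table = code_table),
              class = "mitogenome")
  })
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("mitogenome: %d bp, %d genes, COI at [%d, %d), barcode at [%d, %d) phase %d\n",
              nchar(x$sequence), nrow(x$genes),
              x$coi_interval[1], x$coi_interval[2],
              x$barcode_interval[1], x$barcode_interval[2], x$frame_offset))
  invisible(x)
}

#' Extract the COI barcode query from a mitogenome
#'
#' @param mitogenome a [generate_mitogenome()] object.
#' @param full if `TRUE`, return the full COI gene instead of the 658 bp
#'   barcode window.
#' @return list with `sequence`, `frame_offset` (codon phase of the first
#'   query base) and `offset` (0-based query start on the mitogenome).
#' @export
mito_barcode <- function(mitogenome, full = FALSE) {
  iv <- if (full) mitogenome$coi_interval else mitogenome$barcode_interval
  list(sequence = seq_slice(mitogenome$sequence, iv[1], iv[2]),
       frame_offset = if (full) 0L else mitogenome$frame_offset,
       offset = iv[1])
}

#' Introduce an exact number of substitutions into a DNA segment
#'
#' Exactly `round(d * nchar(seq))` distinct positions are changed, each to a
#' different base; a transition is chosen with probability
#' `kappa / (kappa + 1)`, otherwise one of the two transversions. The model
#' is gap-free, so the Hamming distance of the result from the input equals
#' the requested divergence up to rounding of the site count.
#'
#' @param seq DNA string (A/C/G/T).
#' @param d substituted-site fraction in `[0, 0.5)`.
#' @param kappa transition/transversion rate ratio.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param exclude 0-based positions that must not be substituted.
#' @return list with `sequence` and 0-based `positions` of the
#'   substituted sites.
#' @export
mutate_segment <- function(seq, d, kappa = 2, seed = NULL, exclude = integer(0)) {
  if (d < 0 || d >= 0.5)
    stop("divergence d must lie in [0, 0.5)")
  run <- function() {
    L <- nchar(seq)
    n_sub <- round(d * L)
    if (n_sub == 0)
      return(list(sequence = seq, positions = integer(0)))
    avail <- setdiff(seq_len(L) - 1L, exclude)
    if (length(avail) < n_sub)
      stop("not enough substitutable positions")
    pos <- sort(sample(avail, n_sub))
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    is_ts <- runif(n_sub) < kappa / (kappa + 1)
    for (k in seq_len(n_sub)) {
      b <- bases[pos[k] + 1L]
      if (is_ts[k] && b %in% names(transition)) {
        bases[pos[k] + 1L] <- transition[[b]]
      } else {
        tv <- setdiff(c("A", "C", "G", "T"), c(b, transition[[b]]))
        bases[pos[k] + 1L] <- sample(tv, 1)
      }
    }
    list(sequence = paste(bases, collapse = ""), positions = pos)
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

#' Truncated Pareto length distribution (alpha = 1)
#'
#' The empirical length distribution of COI NUMTs is well approximated by a
#' Pareto distribution with shape 1; lengths are drawn from its truncation
#' to `[min_len, max_len]` by inverse-CDF sampling.
#'
#' `qtrunc_pareto` is the quantile function, `ptrunc_pareto` the CDF.
#'
#' @param u quantile in `[0, 1]`.
#' @param x length in bp.
#' @param min_len,max_len truncation bounds in bp (`20 <= min_len < max_len`).
#' @return `qtrunc_pareto`: length(s) in bp; `ptrunc_pareto`: probability.
#' @examples
#' round(qtrunc_pareto(0.5, 100, 1600))  # 188
#' ptrunc_pareto(300, 100, 1600)         # ~0.711
#' @export
qtrunc_pareto <- function(u, min_len, max_len) {
  stopifnot(min_len >= 20, min_len < max_len)
  min_len / (1 - u * (1 - min_len / max_len))
}

#' @rdname qtrunc_pareto
#' @export
ptrunc_pareto <- function(x, min_len, max_len) {
  stopifnot(min_len >= 20, min_len < max_len)
  pmin(1, pmax(0, (1 - min_len / x) / (1 - min_len / max_len)))
}

#' Sample NUMT lengths from the truncated Pareto model
#'
#' @param n number of draws.
#' @param min_len,max_len truncation bounds in bp.
#' @param seed optional integer seed.
#' @return integer vector of lengths (nearest bp).
#' @export
sample_numt_length <- function(n = 1, min_len = 100, max_len = 1600,
                               seed = NULL) {
  run <- function() as.integer(round(qtrunc_pareto(runif(n), min_len, max_len)))
  if (is.null(seed)) run() else local_seed(seed, run())
}

#' Generate a random nuclear background assembly
#'
#' i.i.d. uniform-composition scaffolds with a configurable GC fraction; no
#' repeat structure is modelled.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length length of each scaffold in bp.
#' @param gc GC fraction.
#' @param seed integer seed.
#' @return a [scaffold_set()].
#' @export
make_background_assembly <- function(n_scaffolds, scaffold_length, gc = 0.4,
                                     seed = 1L) {
  local_seed(seed, {
    seqs <- vapply(seq_len(n_scaffolds),
                   function(i) random_dna(scaffold_length, gc), character(1))
    scaffold_set(sprintf("scaf%d", seq_len(n_scaffolds)), seqs)
  })
}

# gapped "true" alignment of a source segment against its edited copy,
# reconstructed from the recorded indels (positions refer to the source
# segment after substitution, before indel editing)
true_alignment <- function(src, edited_bases, indels) {
  q <- strsplit(src, "", fixed = TRUE)[[1]]
  s <- edited_bases
  if (length(indels) == 0)
    return(list(q = src, s = paste(s, collapse = "")))
  qa <- character(0); sa <- character(0)
  qpos <- 1L; spos <- 1L
  evs <- indels[order(vapply(indels, `[[`, 0, "position"))]
  for (ev in evs) {
    upto <- ev$position  # 0-based position in source-coordinates
    while (qpos <= upto) {
      qa <- c(qa, q[qpos]); sa <- c(sa, s[spos])
      qpos <- qpos + 1L; spos <- spos + 1L
    }
    if (ev$is_insertion) {
      qa <- c(qa, rep("-", ev$length))
      sa <- c(sa, s[spos:(spos + ev$length - 1L)])
      spos <- spos + ev$length
    } else {
      qa <- c(qa, q[qpos:(qpos + ev$length - 1L)])
      sa <- c(sa, rep("-", ev$length))
      qpos <- qpos + ev$length
    }
  }
  while (qpos <= length(q)) {
    qa <- c(qa, q[qpos]); sa <- c(sa, s[spos])
    qpos <- qpos + 1L; spos <- spos + 1L
  }
  list(q = paste(qa, collapse = ""), s = paste(sa, collapse = ""))
}

apply_indels <- function(seq, indels) {
  # indels carry 0-based positions on `seq`; apply right-to-left
  for (ev in rev(indels[order(vapply(indels, `[[`, 0, "position"))])) {
    if (ev$is_insertion) {
      ins <- random_dna(ev$length)
      seq <- paste0(substr(seq, 1, ev$position), ins,
                    substr(seq, ev$position + 1L, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1, ev$position),
                    substr(seq, ev$position + ev$length + 1L, nchar(seq)))
    }
  }
  seq
}

sample_indels <- function(policy, L) {
  if (policy == "none") return(list())
  n_ind <- sample(1:2, 1, prob = c(0.7, 0.3))
  lens_pool <- switch(policy,
    random = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
    frameshift = c(1, 2, 4, 5, 7, 8),
    inframe = c(3, 6, 9))
  w <- 0.5 ^ (lens_pool)  # geometric(0.5) truncated at 9 bp
  out <- list()
  pos_taken <- integer(0)
  for (k in seq_len(n_ind)) {
    len <- sample(lens_pool, 1, prob = w)
    lo <- 6L; hi <- L - 6L - len
    if (hi <= lo) next
    pos <- sample(setdiff(lo:hi, pos_taken), 1)
    pos_taken <- c(pos_taken, (pos - 10L):(pos + 10L))
    out[[length(out) + 1L]] <- list(position = pos, length = len,
                                    is_insertion = runif(1) < 0.5)
  }
  out
}

#' Plant NUMTs into an assembly with full ground truth
#'
#' Each NUMT event copies a source interval from the mitogenome, applies an
#' exact-count substitution model (optionally a planted in-frame premature
#' stop, counted among the substitutions), optionally edits the copy with
#' short indels, optionally duplicates it, and inserts every copy at a
#' uniformly chosen non-overlapping position and strand. The returned truth
#' table lists every planted copy with its final assembly coordinates.
#'
#' The premature-stop flag in the truth table is computed from the edited
#' copy itself: the reconstructed source/copy alignment is screened for an
#' in-frame stop codon in the reading frame of COI, so incidental stops
#' created by substitutions are recorded as well as deliberately planted
#' ones.
#'
#' @param assembly a [scaffold_set()] to insert into.
#' @param mitogenome a [generate_mitogenome()] object.
#' @param n_numts number of NUMT events (before duplication).
#' @param source one of `"mitogenome"`, `"coi"`, `"barcode"`: the region
#'   source intervals are drawn from.
#' @param length_range bp range passed to the truncated-Pareto sampler.
#' @param d_range divergence range; each event draws d uniformly from it.
#' @param kappa transition/transversion ratio for [mutate_segment()].
#' @param indel_policy `"none"`, `"random"`, `"frameshift"` (lengths not a
#'   multiple of 3) or `"inframe"`.
#' @param indel_prob probability that an event carries indels.
#' @param stop_prob probability that an event carries a planted in-frame
#'   premature stop codon.
#' @param copy_range integer range of copies per event (up to 10).
#' @param seed integer seed.
#' @return list with `assembly` (edited scaffold set) and `truth`
#'   (data.frame, one row per planted copy).
#' @export
plant_numts <- function(assembly, mitogenome, n_numts,
                        source = c("mitogenome", "coi", "barcode"),
                        length_range = c(100, 1600), d_range = c(0, 0.36),
                        kappa = 2,
                        indel_policy = c("none", "random", "frameshift", "inframe"),
                        indel_prob = 0, stop_prob = 0,
                        copy_range = c(1, 1), seed = 1L) {
  source <- match.arg(source)
  indel_policy <- match.arg(indel_policy)
  stopifnot(copy_range[2] <= 10)
  truth0 <- data.frame(id = character(0), scaffold_id = character(0),
                       insert_start = integer(0), insert_end = integer(0),
                       strand = character(0), source_start = integer(0),
                       source_end = integer(0), planted_length = integer(0),
                       divergence = numeric(0), n_indels = integer(0),
                       has_frameshift = logical(0), has_planted_stop = logical(0),
                       copy_group = character(0), stringsAsFactors = FALSE)
  if (n_numts == 0)
    return(list(assembly = assembly, truth = truth0))
  region <- switch(source,
    mitogenome = c(0L, nchar(mitogenome$sequence)),
    coi = mitogenome$coi_interval,
    barcode = mitogenome$barcode_interval)
  coi_start <- mitogenome$coi_interval[1]

  local_seed(seed, {
    placements <- list()   # one entry per planted copy
    for (e in seq_len(n_numts)) {
      max_len <- min(length_range[2], region[2] - region[1])
      L <- if (length_range[1] >= max_len) max_len
           else sample_numt_length(1, length_range[1], max_len)
      src_start <- region[1] + sample.int(region[2] - region[1] - L + 1L, 1) - 1L
      src_seq <- seq_slice(mitogenome$sequence, src_start, src_start + L)
      d <- runif(1, d_range[1], d_range[2])

      # planted stop first, so its edited sites count toward the divergence
      stop_pos <- integer(0)
      seg <- src_seq
      if (runif(1) < stop_prob) {
        phase0 <- ((src_start - coi_start) %% 3 + 3) %% 3
        off <- (3 - phase0) %% 3
        n_codon <- (L - off) %/% 3
        if (n_codon >= 4) {
          ci <- sample(2:(n_codon - 2), 1)   # strictly interior codon
          cpos <- off + 3 * (ci - 1)
          old <- substr(seg, cpos + 1, cpos + 3)
          new <- if (substr(old, 1, 1) == "T" && runif(1) < 0.5) "TAG" else "TAA"
          changed <- which(strsplit(old, "")[[1]] != strsplit(new, "")[[1]])
          substr(seg, cpos + 1, cpos + 3) <- new
          stop_pos <- cpos + changed - 1L
        }
      }
      n_target <- round(d * L)
      d_extra <- max(0, n_target - length(stop_pos)) / L
      mut <- mutate_segment(seg, d_extra, kappa, exclude = stop_pos)
      n_sub <- length(mut$positions) + length(stop_pos)

      indels <- if (runif(1) < indel_prob) sample_indels(indel_policy, L) else list()
      edited <- apply_indels(mut$sequence, indels)
      has_fs <- any(vapply(indels, function(ev) ev$length %% 3 != 0, logical(1)))
      aln <- true_alignment(src_seq, strsplit(edited, "", fixed = TRUE)[[1]], indels)
      phase <- ((src_start - coi_start) %% 3 + 3) %% 3
      has_stop <- detect_premature_stop(aln$q, aln$s, phase,
                                        mitogenome$code_table)

      n_copies <- if (copy_range[1] == copy_range[2]) copy_range[1]
                  else sample(copy_range[1]:copy_range[2], 1)
      for (cc in seq_len(n_copies)) {
        placements[[length(placements) + 1L]] <- list(
          id = sprintf("numt%d_c%d", e, cc),
          copy_group = sprintf("numt%d", e),
          sequence = edited, strandless_len = nchar(edited),
          source_start = src_start, source_end = src_start + L,
          divergence = n_sub / L, n_indels = length(indels),
          has_frameshift = has_fs, has_planted_stop = has_stop)
      }
    }

    # choose insertion points in original scaffold coordinates
    scaf_len <- nchar(assembly$sequence)
    if (nrow(assembly) == 0) stop("placement error: empty assembly")
    pts <- vector("list", nrow(assembly))
    for (k in seq_along(placements)) {
      ok <- FALSE
      for (try in 1:200) {
        si <- sample.int(nrow(assembly), 1, prob = scaf_len)
        pt <- sample.int(scaf_len[si] + 1L, 1) - 1L
        if (!pt %in% unlist(pts[[si]])) {
          pts[[si]] <- c(pts[[si]], pt)
          placements[[k]]$scaffold <- si
          placements[[k]]$point <- pt
          placements[[k]]$strand <- sample(c("+", "-"), 1)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("placement error: insufficient scaffold space")
    }

    # apply insertions per scaffold, left to right, tracking coordinate shift
    truth <- list()
    seqs <- assembly$sequence
    for (si in seq_len(nrow(assembly))) {
      idx <- which(vapply(placements, function(p) p$scaffold, 0L) == si)
      if (length(idx) == 0) next
      idx <- idx[order(vapply(placements[idx], function(p) p$point, 0L))]
      shift <- 0L
      s <- seqs[si]
      for (k in idx) {
        p <- placements[[k]]
        ins <- if (p$strand == "-") revcomp(p$sequence) else p$sequence
        at <- p$point + shift
        s <- paste0(substr(s, 1, at), ins, substr(s, at + 1L, nchar(s)))
        truth[[length(truth) + 1L]] <- data.frame(
          id = p$id, scaffold_id = assembly$id[si],
          insert_start = at, insert_end = at + nchar(ins),
          strand = p$strand,
          source_start = p$source_start, source_end = p$source_end,
          planted_length = nchar(ins),
          divergence = p$divergence, n_indels = p$n_indels,
          has_frameshift = p$has_frameshift,
          has_planted_stop = p$has_planted_stop,
          copy_group = p$copy_group, stringsAsFactors = FALSE)
        shift <- shift + nchar(ins)
      }
      seqs[si] <- s
    }
    out <- assembly
    out$sequence <- seqs
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$id), , drop = FALSE]
    rownames(truth) <- NULL
    list(assembly = scaffold_set(out$id, out$sequence, out$description),
         truth = truth)
  })
}

#' Append a residual mitochondrial scaffold to an assembly
#'
#' Emulates the partial or complete mitogenome copies that persist in
#' published assemblies; lengths beyond the mitogenome wrap around the
#' circular sequence. When `labelled`, the scaffold description carries the
#' token "mitochondrion" as assembly pipelines emit it.
#'
#' @param assembly a [scaffold_set()].
#' @param mitogenome a [generate_mitogenome()] object.
#' @param labelled should the FASTA description identify the scaffold as
#'   mitochondrial?
#' @param length scaffold length in bp (200-46,000).
#' @param seed integer seed (start position of the copy).
#' @param id scaffold id; default is unique within the assembly.
#' @return the extended scaffold set.
#' @export
add_residual_mito_scaffolds <- function(assembly, mitogenome, labelled = TRUE,
                                        length = 15000L, seed = 1L, id = NULL) {
  stopifnot(length >= 200, length <= 46000)
  mseq <- mitogenome$sequence
  local_seed(seed, {
    start <- sample.int(nchar(mseq), 1) - 1L
    tandem <- paste(rep(mseq, ceiling((start + length) / nchar(mseq)) + 1L),
                    collapse = "")
    s <- seq_slice(tandem, start, start + length)
    if (is.null(id)) id <- sprintf("scafMT%d", nrow(assembly) + 1L)
    desc <- if (labelled) "mitochondrion, complete genome"
            else "unplaced genomic scaffold"
    scaffold_set(c(assembly$id, id), c(assembly$sequence, s),
                 c(assembly$description, desc))
  })
}

#' Simulate a complete single-species dataset
#'
#' Bundles a mitogenome, a background assembly, planted NUMTs and an
#' optional residual mitochondrial scaffold into one reproducible object.
#'
#' @param seed integer master seed; all stages derive their streams from it.
#' @param n_scaffolds,scaffold_length,gc background assembly parameters.
#' @param mito_length,coi_length,frame_offset mitogenome parameters.
#' @param n_numts,source,length_range,d_range,indel_policy,indel_prob,stop_prob,copy_range
#'   NUMT planting parameters, see [plant_numts()].
#' @param residual_mito `"none"`, `"labelled"` or `"unlabelled"`.
#' @param query_full use the full COI gene rather than the 658 bp barcode as
#'   the stored query.
#' @return object of class `numt_simulation`: list with `assembly`,
#'   `mitogenome`, `query` (sequence + frame), `truth`, `seed`, `config`.
#' @export
simulate_dataset <- function(seed = 1L, n_scaffolds = 4L,
                             scaffold_length = 50000L, gc = 0.4,
                             mito_length = 15500L, coi_length = 1536L,
                             frame_offset = 1L,
                             n_numts = 20L, source = "coi",
                             length_range = c(100, 1536),
                             d_range = c(0.03, 0.30),
                             indel_policy = "none", indel_prob = 0,
                             stop_prob = 0, copy_range = c(1, 1),
                             residual_mito = "none", query_full = FALSE) {
  cfg <- as.list(environment())
  mg <- generate_mitogenome(derive_seed(seed, 1), mito_length, coi_length,
                            frame_offset)
  asm <- make_background_assembly(n_scaffolds, scaffold_length, gc,
                                  derive_seed(seed, 2))
  pl <- plant_numts(asm, mg, n_numts, source = source,
                    length_range = length_range, d_range = d_range,
                    indel_policy = indel_policy, indel_prob = indel_prob,
                    stop_prob = stop_prob, copy_range = copy_range,
                    seed = derive_seed(seed, 3))
  asm <- pl$assembly
  if (residual_mito != "none")
    asm <- add_residual_mito_scaffolds(asm, mg,
                                       labelled = residual_mito == "labelled",
                                       length = min(15000L, 46000L),
                                       seed = derive_seed(seed, 4))
  structure(list(assembly = asm, mitogenome = mg,
                 query = mito_barcode(mg, full = query_full),
                 truth = pl$truth, seed = seed, config = cfg),
            class = "numt_simulation")
}

#' @export
print.numt_simulation <- function(x, ...) {
  cat(sprintf("numt_simulation (seed %d): %d scaffold(s), %d planted NUMT cop(ies)\n",
              x$seed, nrow(x$assembly),
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the assembly and query FASTAs, the mitogenome FASTA with a BED-like
#' gene table, the ground-truth TSV and a JSON echo of the configuration.
#'
#' @param sim a [simulate_dataset()] object.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(assembly = file.path(dir, "assembly.fasta"),
             query = file.path(dir, "query.fasta"),
             mitogenome = file.path(dir, "mitogenome.fasta"),
             genes = file.path(dir, "genes.bed"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  write_fasta(sim$assembly, paths["assembly"])
  write_fasta(scaffold_set("query", sim$query$sequence,
                           sprintf("COI query frame_offset=%d",
                                   sim$query$frame_offset)),
              paths["query"])
  write_fasta(scaffold_set("mitogenome", sim$mitogenome$sequence,
                           "synthetic mitogenome"),
              paths["mitogenome"])
  write_gene_table(sim$mitogenome$genes, "mitogenome", paths["genes"])
  write_truth_table(sim$truth, paths["truth"])
  jsonlite::write_json(sim$config[setdiff(names(sim$config), "")],
                       paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
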