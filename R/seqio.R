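#' Construct a scaffold set
#'
#' A scaffold set is the in-memory form of a (multi-)FASTA assembly: an
#' ordered table of records with a unique `id` (first header token), a free
#' `description` (remainder of the header) and an uppercase DNA `sequence`.
#'
#' @param id character vector of unique scaffold identifiers.
#' @param sequence character vector of DNA sequences (A/C/G/T/N; lowercase
#'   input is normalised to uppercase).
#' @param description character vector of header descriptions (recycled).
#' @return a `data.frame` of class `scaffold_set` with columns `id`,
#'   `description`, `sequence`.
#' @examples
#' scaffold_set(c("s1", "s2"), c("ACGT", "GGGT"))
#' @export
scaffold_set <- function(id, sequence, description = "") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("id and sequence must have equal length")
  if (anyDuplicated(id))
    stop("duplicate scaffold id: ", id[duplicated(id)][1])
  bad <- regexpr("[^ACGTN]", sequence)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("non-IUPAC character in sequence '%s' at position %d",
                 id[i], bad[i]))
  }
  structure(
    data.frame(id = id,
               description = rep_len(as.character(description), length(id)),
               sequence = sequence,
               stringsAsFactors = FALSE),
    class = c("scaffold_set", "data.frame"))
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf("scaffold_set: %d scaffold(s), %s bp total\n",
              nrow(x), format(sum(nchar(x$sequence)), big.mark = ",")))
  if (nrow(x) > 0) {
    show <- utils::head(x, 6)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %-20s %9d bp  %s\n", show$id[i],
                  nchar(show$sequence[i]), show$description[i]))
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' Read a FASTA file into a scaffold set
#'
#' Record order is preserved; the header is split into the id (first
#' whitespace-delimited token) and a description (the rest). Sequences are
#' uppercased. Malformed input (duplicate ids, non-IUPAC characters) is
#' rejected rather than coerced.
#'
#' @param path path to a FASTA file. An empty file yields an empty set.
#' @return a [scaffold_set()].
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0)
    return(scaffold_set(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  scaffold_set(id, as.character(set), description)
}

#' Write a scaffold set as FASTA
#'
#' @param x a [scaffold_set()].
#' @param path output path.
#' @param width line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  seqs <- Biostrings::BStringSet(x$sequence)
  names(seqs) <- ifelse(nzchar(x$description),
                        paste(x$id, x$description), x$id)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Does a scaffold description carry a mitochondrial label?
#'
#' Case-insensitive substring match on "mitochondri", covering the forms
#' "mitochondrion" and "mitochondrial" used in assembly headers.
#'
#' @param description character vector of scaffold descriptions.
#' @return logical vector.
#' @export
is_mito_labelled <- function(description) {
  grepl("mitochondri", description, ignore.case = TRUE)
}

hit_table_cols <- c("query_id", "scaffold_id", "strand",
                    "q_start", "q_end", "s_start", "s_end",
                    "aligned_len", "matches", "identity", "score", "evalue",
                    "q_gapped", "s_gapped")
hit_num_cols <- c("q_start", "q_end", "s_start", "s_end",
                  "aligned_len", "matches", "identity", "score", "evalue")

empty_hit_table <- function() {
  df <- data.frame(query_id = character(0), scaffold_id = character(0),
                   strand = character(0),
                   q_start = numeric(0), q_end = numeric(0),
                   s_start = numeric(0), s_end = numeric(0),
                   aligned_len = numeric(0), matches = numeric(0),
                   identity = numeric(0), score = numeric(0),
                   evalue = numeric(0),
                   q_gapped = character(0), s_gapped = character(0),
                   stringsAsFactors = FALSE)
  structure(df, class = c("numt_hits", "data.frame"))
}

as_hit_table <- function(df) {
  df <- df[, hit_table_cols]
  structure(df, class = c("numt_hits", "data.frame"))
}

#' @export
print.numt_hits <- function(x, ...) {
  cat(sprintf("numt_hits: %d local alignment(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    show <- utils::head(as.data.frame(x)[, c("query_id", "scaffold_id",
        "strand", "s_start", "s_end", "aligned_len", "identity", "evalue")], 10)
    print(show, row.names = FALSE)
    if (nrow(x) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Write / read a hit table
#'
#' Tab-separated with a header row; floating-point columns are printed with
#' six significant digits and survive a round trip unchanged.
#'
#' @param hits a hit table as returned by [find_hits()].
#' @param path file path.
#' @return `read_hit_table` returns the hit table; `write_hit_table`
#'   returns `path` invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- as.data.frame(hits)[, hit_table_cols, drop = FALSE]
  for (cl in c("identity", "score", "evalue"))
    out[[cl]] <- formatC(signif(out[[cl]], 6), format = "g", digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!identical(names(df), hit_table_cols))
    stop("malformed hit table: expected columns ",
         paste(hit_table_cols, collapse = ", "))
  if (nrow(df) == 0) return(empty_hit_table())
  for (cl in hit_num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v))
      stop(sprintf("malformed hit table: non-numeric '%s' at line %d",
                   cl, which(is.na(v))[1] + 1L))
    df[[cl]] <- v
  }
  as_hit_table(df)
}

#' Write / read a gene table (BED-like)
#'
#' Six columns (scaffold, start, end, name, score, strand) with 0-based
#' half-open coordinates, tab-separated, no header.
#'
#' @param genes data.frame with columns `name`, `start`, `end`, `strand`.
#' @param scaffold_id scaffold name to write in column 1.
#' @param path file path.
#' @return `read_gene_table` returns a data.frame with columns
#'   `name`, `start`, `end`, `strand`.
#' @export
write_gene_table <- function(genes, scaffold_id, path) {
  out <- data.frame(chrom = scaffold_id, start = genes$start, end = genes$end,
                    name = genes$name, score = 0L, strand = genes$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 6) stop("malformed gene table: expected 6 columns")
  if (!is.numeric(df[[2]]) || !is.numeric(df[[3]]))
    stop("malformed gene table: non-numeric coordinates")
  data.frame(name = df[[4]], start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), strand = df[[6]],
             stringsAsFactors = FALSE)
}

truth_cols <- c("id", "scaffold_id", "insert_start", "insert_end", "strand",
                "source_start", "source_end", "planted_length",
                "divergence", "n_indels", "has_frameshift",
                "has_planted_stop", "copy_group")

#' Write / read a planted-NUMT ground-truth table
#'
#' One row per planted copy; coordinates 0-based half-open.
#'
#' @param truth ground-truth data.frame from [plant_numts()].
#' @param path file path.
#' @return `read_truth_table` returns the truth data.frame.
#' @export
write_truth_table <- function(truth, path) {
  write.table(as.data.frame(truth)[, truth_cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(df), truth_cols))
    stop("malformed truth table: expected columns ",
         paste(truth_cols, collapse = ", "))
  df$has_frameshift <- as.logical(df$has_frameshift)
  df$has_planted_stop <- as.logical(df$has_planted_stop)
  df
}
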