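# End-to-end orchestration: simulate -> mito-screen -> scan -> classify ->
# window counts -> report, with a config file, a manifest, and the small
# named fixtures the test-suite shares.

default_config <- function() {
  list(seed = 1L,
       n_scaffolds = 4L, scaffold_length = 50000L, gc = 0.4,
       mito_length = 15500L, coi_length = 1536L, frame_offset = 1L,
       n_numts = 20L, source = "coi",
       length_range = c(100, 1536), d_range = c(0.03, 0.30),
       indel_policy = "random", indel_prob = 0.4, stop_prob = 0.2,
       copy_range = c(1, 1), residual_mito = "labelled",
       min_len = 100, min_identity = 0.60, max_evalue = 1e-4,
       otu_threshold = 0.02, n_species = 1L)
}

validate_config <- function(cfg) {
  chk <- function(field, ok) if (!ok) stop("config error: field '", field,
                                           "' is invalid", call. = FALSE)
  chk("seed", is.numeric(cfg$seed) && cfg$seed == round(cfg$seed))
  chk("min_identity", is.numeric(cfg$min_identity) &&
        cfg$min_identity >= 0 && cfg$min_identity <= 1)
  chk("max_evalue", is.numeric(cfg$max_evalue) && cfg$max_evalue > 0)
  chk("min_len", is.numeric(cfg$min_len) && cfg$min_len >= 20)
  chk("otu_threshold", is.numeric(cfg$otu_threshold) &&
        cfg$otu_threshold > 0 && cfg$otu_threshold < 1)
  chk("n_numts", is.numeric(cfg$n_numts) && cfg$n_numts >= 0)
  chk("source", cfg$source %in% c("mitogenome", "coi", "barcode"))
  chk("residual_mito", cfg$residual_mito %in% c("none", "labelled",
                                                "unlabelled"))
  invisible(cfg)
}

#' Run the full NUMT pipeline on a simulated dataset
#'
#' Stages: dataset simulation, mitochondrial-scaffold screen, barcode hit
#' scan, residual-hit filter, NUMT classification, mitogenome-wide window
#' counts, and a report with category counts, protocol exposures and OTU
#' inflation. All stage outputs plus a manifest (config echo, seed,
#' parameter hash, file checksums) are written under `outdir`; rerunning
#' with the same config reproduces identical outputs.
#'
#' @param config a named list, or the path of a YAML file, overriding the
#'   defaults (see the `pipeline` section of the package vignette).
#' @param outdir output directory.
#' @return list of class `numt_pipeline` with the stage objects and the
#'   report, invisibly; files under `outdir`.
#' @export
run_numt_pipeline <- function(config = list(), outdir = tempfile("numtrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  validate_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_dataset(seed = cfg$seed, n_scaffolds = cfg$n_scaffolds,
                          scaffold_length = cfg$scaffold_length, gc = cfg$gc,
                          mito_length = cfg$mito_length,
                          coi_length = cfg$coi_length,
                          frame_offset = cfg$frame_offset,
                          n_numts = cfg$n_numts, source = cfg$source,
                          length_range = cfg$length_range,
                          d_range = cfg$d_range,
                          indel_policy = cfg$indel_policy,
                          indel_prob = cfg$indel_prob,
                          stop_prob = cfg$stop_prob,
                          copy_range = cfg$copy_range,
                          residual_mito = cfg$residual_mito)
  paths <- write_dataset(sim, outdir)

  scr <- mito_screen(sim$assembly, sim$mitogenome)
  write_fasta(scr$assembly, file.path(outdir, "cleaned.fasta"))

  hits <- find_hits(sim$query$sequence, scr$assembly,
                    min_len = cfg$min_len, min_identity = cfg$min_identity,
                    max_evalue = cfg$max_evalue, query_id = "coi_barcode")
  hits <- filter_residual_hits(hits, query_len = nchar(sim$query$sequence))
  write_hit_table(hits, file.path(outdir, "hits.tsv"))

  records <- classify_numts(hits, query = sim$query$sequence,
                            scaffolds = scr$assembly,
                            frame_offset = sim$query$frame_offset,
                            code_table = sim$mitogenome$code_table)
  write.table(as.data.frame(records)[, setdiff(names(records),
                                               c("q_gapped", "s_gapped"))],
              file.path(outdir, "numts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  wc <- windowed_counts(scr$assembly, sim$mitogenome,
                        min_len = cfg$min_len,
                        min_identity = cfg$min_identity,
                        max_evalue = cfg$max_evalue)

  cat_counts <- table(factor(records$category, levels = paste0("C", 1:5)))
  counts <- c(as.list(cat_counts), list(C5star = sum(records$is_c5_star)))
  protocols <- c("full", "dual", "five", "metabarcoding", "edna")
  exposure <- lapply(protocols, function(p)
    protocol_exposure(counts, p, cfg$n_species))
  names(exposure) <- protocols

  report <- list(
    n_hits = nrow(hits), n_numts = nrow(records),
    category_counts = as.list(cat_counts), c5_star = sum(records$is_c5_star),
    ipsc_fraction = if (nrow(records)) mean(records$has_ipsc) else NA,
    window_mean = wc$mean_count, coi_count = wc$coi_count,
    protocol_exposure = exposure)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "numtrisk",
    version = as.character(utils::packageVersion("numtrisk")),
    seed = cfg$seed,
    config = cfg,
    parameter_hash = substr(tools::md5sum(paths[["config"]]), 1, 12),
    checksums = as.list(tools::md5sum(
      list.files(outdir, full.names = TRUE,
                 pattern = "\\.(fasta|tsv|bed|json)$"))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  manifest$checksums[["manifest.json"]] <- NULL
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(list(sim = sim, screen = scr, hits = hits,
                           records = records, windows = wc, report = report,
                           outdir = outdir),
                      class = "numt_pipeline"))
}

#' @export
print.numt_pipeline <- function(x, ...) {
  cat(sprintf("numt_pipeline: %d NUMT record(s), %d C5*, outputs in %s\n",
              x$report$n_numts, x$report$c5_star, x$outdir))
  invisible(x)
}

#' Deterministic named fixtures for tests and examples
#'
#' * `"c5star-pair"`: an assembly with two full-length (barcode-spanning)
#'   NUMTs at ~5% and ~10% divergence, no indels or stops.
#' * `"ten-copies"`: one NUMT duplicated into ten identical copies.
#' * `"residual-mito"`: an assembly containing one labelled and one
#'   unlabelled residual mitogenome copy.
#' * `"empty"`: an assembly with no NUMTs.
#'
#' @param name fixture name.
#' @return a [simulate_dataset()] object.
#' @export
make_fixture <- function(name) {
  fixtures <- c("c5star-pair", "ten-copies", "residual-mito", "empty")
  if (!name %in% fixtures)
    stop("unknown fixture '", name, "'; valid fixtures: ",
         paste(fixtures, collapse = ", "))
  switch(name,
    "c5star-pair" = {
      sim <- simulate_dataset(seed = 101L, n_scaffolds = 2L,
                              scaffold_length = 20000L, n_numts = 0L)
      # full-length barcode copies without an IPSC: substitutions can create
      # incidental in-frame stops, so walk the (deterministic) seed sequence
      # until both planted copies are stop-free
      plant_clean <- function(asm, d, seed0) {
        for (k in 0:50) {
          p <- plant_numts(asm, sim$mitogenome, 1L, source = "barcode",
                           length_range = c(658, 658), d_range = c(d, d),
                           seed = seed0 + k)
          if (!p$truth$has_planted_stop && !p$truth$has_frameshift) return(p)
        }
        stop("no stop-free planting found")   # unreachable in practice
      }
      p1 <- plant_clean(sim$assembly, 0.05, 102L)
      p2 <- plant_clean(p1$assembly, 0.10, 200L)
      p2$truth$id[1] <- "numt2_c1"; p2$truth$copy_group[1] <- "numt2"
      sim$assembly <- p2$assembly
      sim$truth <- rbind(p1$truth, p2$truth)
      sim
    },
    "ten-copies" = {
      sim <- simulate_dataset(seed = 104L, n_scaffolds = 3L,
                              scaffold_length = 30000L, n_numts = 1L,
                              source = "barcode", length_range = c(658, 658),
                              d_range = c(0.05, 0.05), copy_range = c(10, 10))
      sim
    },
    "residual-mito" = {
      sim <- simulate_dataset(seed = 105L, n_scaffolds = 2L,
                              scaffold_length = 20000L, n_numts = 5L,
                              residual_mito = "labelled")
      sim$assembly <- add_residual_mito_scaffolds(sim$assembly,
                                                  sim$mitogenome,
                                                  labelled = FALSE,
                                                  length = 15000L,
                                                  seed = 106L)
      sim
    },
    "empty" = simulate_dataset(seed = 107L, n_scaffolds = 2L,
                               scaffold_length = 20000L, n_numts = 0L))
}
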