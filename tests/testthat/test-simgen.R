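test_that("generated mitogenomes satisfy their structural invariants", {
  mg <- generate_mitogenome(seed = 2, length = 15000, coi_length = 1536,
                            frame_offset = 1)
  expect_equal(nchar(mg$sequence), 15000)
  expect_equal(mg$barcode_interval[2] - mg$barcode_interval[1], 658)
  expect_true(mg$barcode_interval[1] >= mg$coi_interval[1] &&
                mg$barcode_interval[2] <= mg$coi_interval[2])
  expect_equal(sum(mg$genes$type == "pcg"), 13)
  expect_equal(sum(mg$genes$type == "rrna"), 2)
  # phase of the first barcode base within COI
  expect_equal((mg$barcode_interval[1] - mg$coi_interval[1]) %% 3, 1)
  # no internal stop in any protein-coding gene read on its own strand
  for (i in which(mg$genes$type == "pcg")) {
    g <- substr(mg$sequence, mg$genes$start[i] + 1, mg$genes$end[i])
    if (mg$genes$strand[i] == "-") g <- rc(g)
    expect_false(grepl("*", translate_dna(g), fixed = TRUE))
  }
})

test_that("mitogenome generation is deterministic and validates sizing", {
  expect_identical(generate_mitogenome(1)$sequence,
                   generate_mitogenome(1)$sequence)
  expect_false(identical(generate_mitogenome(1)$sequence,
                         generate_mitogenome(2)$sequence))
  expect_error(generate_mitogenome(1, length = 12000, coi_length = 1536),
               "too small")
})

test_that("mutate_segment changes an exact count of sites at the ts/tv ratio", {
  seq0 <- local({ set.seed(5); random_dna_str(658) })
  m0 <- mutate_segment(seq0, 0, kappa = 2, seed = 1)
  expect_identical(m0$sequence, seq0)
  expect_length(m0$positions, 0)

  m <- mutate_segment(seq0, 0.10, kappa = 2, seed = 1)
  expect_length(m$positions, 66)   # round(0.10 * 658)
  a <- strsplit(seq0, "")[[1]]; b <- strsplit(m$sequence, "")[[1]]
  expect_equal(which(a != b) - 1L, m$positions)

  # transition fraction ~ kappa/(kappa+1) = 2/3 within 3 sigma of binomial
  seq1 <- local({ set.seed(6); random_dna_str(6000) })
  m2 <- mutate_segment(seq1, 0.12, kappa = 2, seed = 2)
  n_sub <- length(m2$positions)
  expect_equal(n_sub, 720)
  a <- strsplit(seq1, "")[[1]]; b <- strsplit(m2$sequence, "")[[1]]
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- ts[a[m2$positions + 1]] == b[m2$positions + 1]
  p <- 2 / 3
  expect_lt(abs(mean(is_ts) - p), 3 * sqrt(p * (1 - p) / n_sub))

  expect_error(mutate_segment(seq0, 0.5), "\\[0, 0.5\\)")
})

test_that("truncated Pareto sampler matches its closed-form CDF", {
  expect_equal(round(qtrunc_pareto(0.5, 100, 1600)), 188)
  expect_equal(qtrunc_pareto(0, 100, 1600), 100)
  expect_equal(ptrunc_pareto(300, 100, 1600), (1 - 1 / 3) / (1 - 100 / 1600))

  x <- sample_numt_length(10000, 100, 1600, seed = 3)
  expect_true(all(x >= 100 & x <= 1600))
  # chi-square goodness of fit on quantile bins (alpha = 0.01)
  qs <- qtrunc_pareto(seq(0, 1, by = 0.1), 100, 1600)
  obs <- table(cut(x, breaks = qs, include.lowest = TRUE))
  p <- diff(ptrunc_pareto(qs, 100, 1600))
  gof <- suppressWarnings(chisq.test(obs, p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)
})

test_that("plant_numts propagates policies into the truth table", {
  sim0 <- simulate_dataset(seed = 9, n_scaffolds = 2, scaffold_length = 20000,
                           n_numts = 0)
  pl0 <- plant_numts(sim0$assembly, sim0$mitogenome, 0, seed = 1)
  expect_identical(pl0$assembly$sequence, sim0$assembly$sequence)
  expect_equal(nrow(pl0$truth), 0)

  # divergence-free barcode-source planting: no indels, no stops possible
  pl <- plant_numts(sim0$assembly, sim0$mitogenome, 20, source = "barcode",
                    length_range = c(100, 658), d_range = c(0, 0), seed = 2)
  expect_equal(nrow(pl$truth), 20)
  expect_false(any(pl$truth$has_frameshift))
  expect_false(any(pl$truth$has_planted_stop))
  expect_true(all(pl$truth$n_indels == 0))

  # every planted copy is present verbatim at its recorded coordinates
  for (k in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[k, ]
    ins <- substr(pl$assembly$sequence[pl$assembly$id == tr$scaffold_id],
                  tr$insert_start + 1, tr$insert_end)
    if (tr$strand == "-") ins <- rc(ins)
    src <- substr(sim0$mitogenome$sequence, tr$source_start + 1, tr$source_end)
    expect_identical(ins, src)   # d = 0, no indels
  }

  # frameshift flag is structural: indels forced to non-multiples of three
  plf <- plant_numts(sim0$assembly, sim0$mitogenome, 15, source = "coi",
                     length_range = c(150, 600), d_range = c(0.05, 0.15),
                     indel_policy = "frameshift", indel_prob = 1, seed = 3)
  expect_true(all(plf$truth$has_frameshift))
  # in-frame policy never sets the frameshift flag
  pli <- plant_numts(sim0$assembly, sim0$mitogenome, 15, source = "coi",
                     length_range = c(150, 600), d_range = c(0.05, 0.15),
                     indel_policy = "inframe", indel_prob = 1, seed = 4)
  expect_false(any(pli$truth$has_frameshift))
})

test_that("copy duplication shares a copy group across identical copies", {
  sim <- make_fixture("ten-copies")
  expect_equal(nrow(sim$truth), 10)
  expect_equal(length(unique(sim$truth$copy_group)), 1)
  expect_equal(length(unique(sim$truth$id)), 10)
})

test_that("gap-free planted NUMTs have p-distance equal to planted divergence", {
  sim0 <- simulate_dataset(seed = 12, n_scaffolds = 2,
                           scaffold_length = 20000, n_numts = 0)
  pl <- plant_numts(sim0$assembly, sim0$mitogenome, 10, source = "coi",
                    length_range = c(200, 800), d_range = c(0.05, 0.3),
                    seed = 5)
  for (k in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[k, ]
    ins <- substr(pl$assembly$sequence[pl$assembly$id == tr$scaffold_id],
                  tr$insert_start + 1, tr$insert_end)
    if (tr$strand == "-") ins <- rc(ins)
    src <- substr(sim0$mitogenome$sequence, tr$source_start + 1, tr$source_end)
    a <- strsplit(ins, "")[[1]]; b <- strsplit(src, "")[[1]]
    expect_equal(mean(a != b), tr$divergence,
                 tolerance = 1 / tr$planted_length)
  }
})

test_that("residual mitochondrial scaffolds carry the expected label and length", {
  sim0 <- simulate_dataset(seed = 13, n_scaffolds = 1,
                           scaffold_length = 5000, n_numts = 0)
  a1 <- add_residual_mito_scaffolds(sim0$assembly, sim0$mitogenome,
                                    labelled = TRUE, length = 11300, seed = 1)
  expect_equal(nrow(a1), 2)
  expect_match(a1$description[2], "mitochondrion")
  expect_equal(nchar(a1$sequence[2]), 11300)

  a2 <- add_residual_mito_scaffolds(sim0$assembly, sim0$mitogenome,
                                    labelled = FALSE, length = 15000, seed = 2)
  expect_false(is_mito_labelled(a2$description[2]))

  a3 <- add_residual_mito_scaffolds(sim0$assembly, sim0$mitogenome,
                                    labelled = TRUE, length = 45500, seed = 3)
  expect_equal(nchar(a3$sequence[2]), 45500)
  expect_error(add_residual_mito_scaffolds(sim0$assembly, sim0$mitogenome,
                                           length = 46500))
})

test_that("dataset simulation is byte-identical under a fixed seed", {
  s1 <- simulate_dataset(seed = 4, n_scaffolds = 2, scaffold_length = 10000,
                         n_numts = 5)
  s2 <- simulate_dataset(seed = 4, n_scaffolds = 2, scaffold_length = 10000,
                         n_numts = 5)
  expect_identical(s1$assembly$sequence, s2$assembly$sequence)
  expect_identical(s1$truth, s2$truth)

  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in c("assembly.fasta", "truth.tsv", "mitogenome.fasta", "genes.bed"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
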