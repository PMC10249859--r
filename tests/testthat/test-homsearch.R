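test_that("smith_waterman recovers exact matches with full score", {
  h <- smith_waterman("ACGTACGT", "TTTTACGTACGTTTTT")
  expect_equal(h$score, 16)   # 8 x match(+2)
  expect_equal(h$identity, 1.0)
  expect_equal(h$s_end - h$s_start, 8)
  expect_identical(h$q_gapped, "ACGTACGT")
  expect_error(smith_waterman(strrep("A", 1.1e5), "ACGT"), "100 kb")
})

test_that("reverse-complement homology is only found on the minus strand", {
  set.seed(31)
  q <- random_dna_str(60)
  subject <- paste0(random_dna_str(50), rc(q), random_dna_str(50))
  fwd <- smith_waterman(q, subject)
  expect_true(is.null(fwd) || fwd$score < 40)
  rev <- smith_waterman(q, subject, strand = "-")
  expect_equal(rev$score, 120)
  expect_equal(c(rev$s_start, rev$s_end), c(50, 110))
})

test_that("alignment scores agree with an independent DP oracle", {
  set.seed(32)
  for (k in 1:12) {
    q <- random_dna_str(sample(30:120, 1))
    s <- random_dna_str(sample(30:120, 1))
    h <- smith_waterman(q, s)
    expect_equal(if (is.null(h)) 0 else h$score, sw_score_oracle(q, s))
  }
})

test_that("find_hits locates planted copies and reports accurate intervals", {
  sim <- simulate_dataset(seed = 33, n_scaffolds = 2, scaffold_length = 30000,
                          n_numts = 0)
  # exact full barcode copy
  pl <- plant_numts(sim$assembly, sim$mitogenome, 1, source = "barcode",
                    length_range = c(658, 658), d_range = c(0, 0), seed = 1)
  hits <- find_hits(sim$query$sequence, pl$assembly)
  expect_equal(nrow(hits), 1)
  expect_gte(hits$identity, 0.99)
  expect_lte(abs(hits$s_start - pl$truth$insert_start), 5)
  expect_lte(abs(hits$s_end - pl$truth$insert_end), 5)

  # 120 bp copy at 25% divergence is still detected (identity >= 0.60)
  pl2 <- plant_numts(sim$assembly, sim$mitogenome, 1, source = "barcode",
                     length_range = c(120, 120), d_range = c(0.25, 0.25),
                     seed = 2)
  hits2 <- find_hits(sim$query$sequence, pl2$assembly)
  expect_equal(nrow(hits2), 1)
  expect_gte(hits2$identity, 0.60)
  # and its score never exceeds the exact aligner's on the same region
  scaf <- pl2$assembly$sequence[pl2$assembly$id == hits2$scaffold_id]
  win <- substr(scaf, max(1, hits2$s_start - 50), hits2$s_end + 50)
  if (hits2$strand == "-") win <- rc(win)
  expect_lte(hits2$score, smith_waterman(sim$query$sequence, win)$score)

  expect_equal(nrow(find_hits(sim$query$sequence,
                              scaffold_set(character(0), character(0)))), 0)
  expect_error(find_hits("ACGT", sim$assembly), "query length")
})

test_that("random sequence yields no significant hits at the default E-value", {
  set.seed(34)
  scaffolds <- scaffold_set(sprintf("r%d", 1:30),
                            vapply(1:30, function(i) random_dna_str(5000),
                                   character(1)))
  q <- random_dna_str(658)
  hits <- find_hits(q, scaffolds)
  expect_lte(nrow(hits), 1)   # ~0.1 false hits per Mb allows a rare one
})

test_that("two nearby insertions yield two hits, overlapping duplicates merge", {
  sim <- simulate_dataset(seed = 35, n_scaffolds = 1, scaffold_length = 4000,
                          n_numts = 0)
  bar <- sim$query$sequence
  scaf <- sim$assembly$sequence[1]
  frag1 <- substr(bar, 1, 300)
  frag2 <- substr(bar, 301, 658)
  # two fragments 500 bp apart share one seed window
  s <- paste0(substr(scaf, 1, 1000), frag1,
              substr(scaf, 1001, 1500), frag2,
              substr(scaf, 1501, 4000))
  hits <- find_hits(bar, scaffold_set("s", s))
  expect_equal(nrow(hits), 2)
  expect_true(all(abs(sort(hits$q_start) - c(0, 300)) <= 10))
})

test_that("Karlin calibration is deterministic and in a plausible range", {
  k1 <- calibrate_karlin(seed = 7, n_pairs = 60, len = 300)
  k2 <- calibrate_karlin(seed = 7, n_pairs = 60, len = 300)
  expect_identical(k1, k2)
  expect_gt(k1$lambda, 0.2)
  expect_lt(k1$lambda, 1.5)
  expect_gt(k1$K, 0)
})

test_that("planted-NUMT recall and specificity hold on a small corpus", {
  sim <- simulate_dataset(seed = 36, n_scaffolds = 6, scaffold_length = 60000,
                          n_numts = 60, source = "coi",
                          length_range = c(100, 1536),
                          d_range = c(0.03, 0.30), query_full = TRUE)
  hits <- filter_residual_hits(find_hits(sim$query$sequence, sim$assembly),
                               query_len = nchar(sim$query$sequence))
  recs <- classify_numts(hits, query = sim$query$sequence,
                         scaffolds = sim$assembly)
  truth <- sim$truth[sim$truth$planted_length >= 100, ]
  ev <- evaluate_against_truth(recs, truth)
  expect_gte(ev$recall, 0.90)
  expect_gte(ev$precision, 0.95)
})
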