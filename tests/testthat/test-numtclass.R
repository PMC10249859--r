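mk_hit <- function(q_cov, identity, q_start = 0) {
  h <- data.frame(query_id = "q", scaffold_id = "s", strand = "+",
                  q_start = q_start, q_end = q_start + q_cov,
                  s_start = 1000, s_end = 1000 + q_cov,
                  aligned_len = q_cov, matches = round(identity * q_cov),
                  identity = identity, score = 100, evalue = 1e-20,
                  q_gapped = strrep("A", q_cov), s_gapped = strrep("A", q_cov),
                  stringsAsFactors = FALSE)
  structure(h, class = c("numt_hits", "data.frame"))
}

test_that("residual-mitochondrial hit filter applies the coverage/identity rule", {
  hits <- rbind(mk_hit(658, 0.995),   # full coverage, near-identical: drop
                mk_hit(657, 1.000),   # within 1 bp of full coverage: drop
                mk_hit(658, 0.980),   # diverged: keep
                mk_hit(300, 0.995))   # partial coverage: keep
  kept <- filter_residual_hits(structure(hits,
            class = c("numt_hits", "data.frame")), query_len = 658)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$q_end - kept$q_start, c(658, 300))
})

test_that("length categories match the C1-C5 bounds", {
  expect_equal(assign_category(c(99, 100, 150, 151, 300, 301, 450, 451,
                                 600, 601, 658, 754)),
               c(NA, "C1", "C1", "C2", "C2", "C3", "C3", "C4",
                 "C4", "C5", "C5", "C5"))
  expect_error(assign_category(-1), "non-negative")
})

test_that("frameshift detection follows the per-gap multiple-of-three rule", {
  # single 3 bp deletion: in-frame
  expect_false(detect_frameshift("ACGTTTACG", "ACG---ACG"))
  # single 1 bp insertion: frameshift
  expect_true(detect_frameshift("ACG-ACGT", "ACGTACGT"))
  # 2 bp + 1 bp gaps: frame restored overall, still counted per gap
  expect_true(detect_frameshift("ACGTTACG-TT", "ACG--ACGTTT"))
  expect_false(detect_frameshift("ACGTACGT", "ACGTACGT"))
})

test_that("premature-stop screen translates in the query frame (table 5)", {
  # in-frame TAA mid-sequence
  q <- strrep("ATT", 10)
  s <- paste0(strrep("ATT", 4), "TAA", strrep("ATT", 5))
  expect_true(detect_premature_stop(q, s, q_phase = 0))
  # AGA is serine under the invertebrate mitochondrial code, not a stop
  s2 <- paste0(strrep("ATT", 4), "AGA", strrep("ATT", 5))
  expect_false(detect_premature_stop(q, s2, q_phase = 0))
  # TGA codes tryptophan, not a stop
  s3 <- paste0(strrep("ATT", 4), "TGA", strrep("ATT", 5))
  expect_false(detect_premature_stop(q, s3, q_phase = 0))
  # a terminal TAA is not premature
  s4 <- paste0(strrep("ATT", 9), "TAA")
  expect_false(detect_premature_stop(q, s4, q_phase = 0))
  # phase shifts the codon grid: same alignment, different frame
  expect_false(detect_premature_stop(q, s, q_phase = 1))
  # frame re-anchors to the query after an indel
  qg <- paste0(strrep("ATT", 4), "-", strrep("ATT", 6))
  sg <- paste0(strrep("ATT", 4), "G", "TAA", strrep("ATT", 5))
  expect_true(detect_premature_stop(qg, sg, q_phase = 0))
  # too-short span: warning and FALSE
  expect_warning(out <- detect_premature_stop("ATTA", "ATTA", 0), "codons")
  expect_false(out)
})

test_that("classification recovers planted category, divergence and flags", {
  sim <- simulate_dataset(seed = 41, n_scaffolds = 2, scaffold_length = 30000,
                          n_numts = 0)
  pl <- plant_numts(sim$assembly, sim$mitogenome, 1, source = "coi",
                    length_range = c(400, 400), d_range = c(0.08, 0.08),
                    seed = 6)
  hits <- find_hits(mito_barcode(sim$mitogenome, full = TRUE)$sequence,
                    pl$assembly)
  recs <- classify_numts(hits, scaffolds = pl$assembly,
                         query = mito_barcode(sim$mitogenome, full = TRUE)$sequence)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$category, "C3")
  expect_equal(recs$divergence, 8.0, tolerance = 0.3 / 8)
  # full-length barcode-spanning NUMTs without IPSC at > 2% divergence are C5*
  c5 <- make_fixture("c5star-pair")
  h2 <- find_hits(c5$query$sequence, c5$assembly)
  h2 <- filter_residual_hits(h2)
  r2 <- classify_numts(h2, query = c5$query$sequence, scaffolds = c5$assembly,
                       frame_offset = c5$query$frame_offset)
  expect_equal(nrow(r2), 2)
  expect_true(all(r2$category == "C5"))
  expect_true(all(r2$is_c5_star == !r2$has_ipsc))
  expect_gte(sum(r2$is_c5_star), 1)
})

test_that("a planted frameshift indel flags the record as IPSC", {
  sim <- simulate_dataset(seed = 43, n_scaffolds = 2, scaffold_length = 30000,
                          n_numts = 0)
  pl <- plant_numts(sim$assembly, sim$mitogenome, 5, source = "barcode",
                    length_range = c(658, 658), d_range = c(0.05, 0.05),
                    indel_policy = "frameshift", indel_prob = 1, seed = 7)
  hits <- filter_residual_hits(find_hits(sim$query$sequence, pl$assembly))
  recs <- classify_numts(hits, query = sim$query$sequence,
                         scaffolds = pl$assembly,
                         frame_offset = sim$query$frame_offset)
  expect_gte(nrow(recs), 4)
  expect_true(all(recs$has_frameshift))
  expect_true(all(recs$has_ipsc))
  expect_false(any(recs$is_c5_star))
})

test_that("recovery metrics compute matching, precision and recall correctly", {
  truth <- data.frame(id = sprintf("t%d", 1:50), scaffold_id = "s",
                      insert_start = (0:49) * 1000,
                      insert_end = (0:49) * 1000 + 400,
                      strand = "+", source_start = 0, source_end = 400,
                      planted_length = 400, divergence = 0.10, n_indels = 0,
                      has_frameshift = FALSE, has_planted_stop = FALSE,
                      copy_group = sprintf("t%d", 1:50))
  recs <- data.frame(scaffold_id = "s", s_start = truth$insert_start,
                     s_end = truth$insert_end, divergence = 10,
                     has_ipsc = FALSE)
  ev <- evaluate_against_truth(recs, truth)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$precision, 1.0)
  expect_equal(unname(ev$ipsc["TN"]), 50L)
  expect_equal(ev$divergence_mae, 0)

  # one spurious record: precision 50/51
  recs2 <- rbind(recs, data.frame(scaffold_id = "s", s_start = 90000,
                                  s_end = 90400, divergence = 5,
                                  has_ipsc = TRUE))
  ev2 <- evaluate_against_truth(recs2, truth)
  expect_equal(ev2$precision, 50 / 51)
  expect_equal(ev2$recall, 1.0)

  # a record overlapping less than half of the truth interval does not match
  recs3 <- data.frame(scaffold_id = "s", s_start = 0, s_end = 150,
                      divergence = 10, has_ipsc = FALSE)
  ev3 <- evaluate_against_truth(recs3, truth[1, ])
  expect_equal(ev3$recall, 0)
})
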