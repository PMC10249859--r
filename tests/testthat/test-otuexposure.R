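test_that("category exposures reproduce the midpoint model", {
  expect_equal(category_exposure(100, 150), 0.19)
  expect_equal(category_exposure(151, 300), 0.34)
  expect_equal(category_exposure(301, 450), 0.57)
  expect_equal(category_exposure(451, 600), 0.80)
  expect_equal(category_exposure(601, 661), 0.96)
  expect_equal(category_exposure(658, 658), 1.00)
})

test_that("protocol exposure arithmetic follows counts x exposure", {
  # single full-length amplicon: only C5* NUMTs, at exposure 1
  full <- protocol_exposure(c(C5star = 226), "full", 668)
  expect_equal(full$amplifiable, 226)
  expect_equal(round(full$per_species, 2), 0.34)

  # two mid-length amplicons expose C3-C5 at midpoint exposures
  dual <- protocol_exposure(c(C3 = 238, C4 = 135, C5 = 373), "dual", 668)
  expect_equal(dual$amplifiable, 238 * 0.57 + 135 * 0.80 + 373 * 0.96)
  expect_equal(dual$amplifiable, 601.74)
  expect_equal(dual$per_species, 601.74 / 668 * 2)

  # empirical category means may override the midpoint exposures
  emp <- protocol_exposure(c(C3 = 238, C4 = 135, C5 = 373), "dual", 668,
                           exposure = c(C3 = 0.5, C4 = 0.75, C5 = 0.9))
  expect_equal(emp$amplifiable, 238 * 0.5 + 135 * 0.75 + 373 * 0.9)

  zero <- protocol_exposure(c(C1 = 0, C2 = 0, C3 = 0, C4 = 0, C5 = 0),
                            "five", 100)
  expect_equal(zero$amplifiable, 0)
  expect_equal(zero$per_species, 0)

  spec <- protocol_spec("edna")
  expect_equal(spec$n_amplicons, 1L)
  expect_equal(unname(spec$exposure),  c(0.19, 0.34, 0.57, 0.80, 0.96))
})

test_that("p-distance matrices count mismatches over comparable columns", {
  s1 <- strrep("ACGT", 165)                      # 660 bp
  s2 <- s1; substr(s2, 1, 1) <- "G"
  d <- pdistance_matrix(c(a = s1, b = s1, c = s2))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1 / 660)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))

  # gaps and Ns are excluded pairwise
  g1 <- paste0("--", substr(s1, 3, 660))
  d2 <- pdistance_matrix(c(a = s1, g = g1))
  expect_equal(d2["a", "g"], 0)

  expect_error(pdistance_matrix(c(a = "----", b = "AAAA")), "comparable")
})

test_that("single-linkage OTUs are the connected components at the threshold", {
  d <- matrix(c(0, .01, .03, .01, 0, .01, .03, .01, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p <- single_linkage_otus(d, 0.02)
  expect_equal(p$n_otus, 1)   # chaining through B

  d5 <- matrix(0.05, 4, 4); diag(d5) <- 0
  expect_equal(single_linkage_otus(d5, 0.02)$n_otus, 4)

  # 9 identical + 1 at 0.004: one OTU
  d10 <- matrix(0, 10, 10); d10[10, ] <- d10[, 10] <- 0.004; d10[10, 10] <- 0
  expect_equal(single_linkage_otus(d10, 0.02)$n_otus, 1)
})

test_that("clustering equals brute-force components on random matrices", {
  set.seed(71)
  # exhaustive over all graphs on 4 sequences
  for (mask in 0:63) {
    d <- matrix(0.05, 4, 4); diag(d) <- 0
    e <- which(upper.tri(d))
    on <- as.logical(bitwAnd(mask, 2^(0:5)))
    d[e[on]] <- 0.01
    d <- pmin(d, t(d))
    p <- single_linkage_otus(d, 0.02)
    expect_equal(p$n_otus, max(components_oracle(d, 0.02)))
    expect_equal(unname(p$membership),
                 as.integer(components_oracle(d, 0.02)))
  }
  # random matrices up to size 12
  for (r in 1:40) {
    n <- sample(2:12, 1)
    d <- matrix(runif(n * n, 0, 0.06), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    p <- single_linkage_otus(d, 0.02)
    expect_equal(p$n_otus, max(components_oracle(d, 0.02)))
  }
  # OTU count is non-increasing in the threshold
  d <- matrix(runif(100, 0, 0.08), 10, 10); d <- (d + t(d)) / 2; diag(d) <- 0
  counts <- vapply(c(0.005, 0.01, 0.02, 0.04, 0.08),
                   function(h) single_linkage_otus(d, h)$n_otus, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("duplicated-NUMT groups cluster into exactly their group count", {
  set.seed(72)
  base <- vapply(1:3, function(i) random_dna_str(658), character(1))
  seqs <- unlist(lapply(base, function(b) {
    vapply(1:4, function(j)
      mutate_segment(b, 0.008, seed = NULL)$sequence, character(1))
  }))
  names(seqs) <- sprintf("s%d", seq_along(seqs))
  p <- single_linkage_otus(pdistance_matrix(seqs), 0.02)
  expect_equal(p$n_otus, 3)
})

test_that("conversion, inflation and PCR arithmetic are exact", {
  expect_identical(conversion_percentage(632, 668), 95L)
  expect_identical(conversion_percentage(10, 10), 100L)
  expect_identical(conversion_percentage(1, 4), 25L)
  expect_error(conversion_percentage(5, 4), "exceed")

  expect_identical(inflation_percent(139, 632), 22L)
  expect_identical(inflation_percent(0, 632), 0L)
  expect_identical(inflation_percent(632, 632), 100L)
  expect_error(inflation_percent(10, 0), "positive")

  expect_equal(pcr_copy_ratio(60000, 0.005, 2), 150)
  expect_equal(pcr_copy_ratio(1000, 0.01, 2), 5)
  expect_equal(pcr_copy_ratio(60000, 0, 2), 0)
  expect_error(pcr_copy_ratio(60000, 0.005, 0), "positive")

  expect_equal(pcr_trajectory(150, 1.0, 35), 150)
  expect_equal(pcr_trajectory(150, 1.2, 0), 150)
  expect_equal(pcr_trajectory(150, 1.2, 35), 150 / 1.2^35)
  expect_lt(pcr_trajectory(150, 1.2, 35), 1)   # the NUMT dominates
})
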