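# Independent oracles used to validate the package's own implementations.

# Plain affine-gap Smith-Waterman score by direct dynamic programming
# (matrix recursion, score only) — independent of the package's C++ path.
sw_score_oracle <- function(query, subject, match = 2, mismatch = -3,
                            gap_open = 5, gap_ext = 2) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(s)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)  # gap in query
  F <- matrix(-Inf, m + 1, n + 1)  # gap in subject
  go <- gap_open + gap_ext
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - gap_ext)
      sub <- if (q[i - 1] == s[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Connected components of the graph with edges d <= threshold, by
# breadth-first search — the oracle for single-linkage OTU clustering.
components_oracle <- function(d, threshold) {
  n <- nrow(d)
  adj <- d <= threshold
  diag(adj) <- TRUE
  comp <- rep(0L, n)
  k <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    k <- k + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0) next
      comp[u] <- k
      queue <- c(queue, which(adj[u, ] & comp == 0))
    }
  }
  comp
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}
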