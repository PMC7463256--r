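test_that("identical sequences have distance zero and NA pairs are flagged", {
  s <- strrep("ACGT", 250)
  expect_equal(as.numeric(f84_distance(s, s)), 0)
  d <- f84_distance("NNNN", "ACGT")
  expect_true(is.na(d))
  expect_equal(attr(d, "reason"), "no_sites")
  expect_error(f84_distance("ACGT", "ACG"), "equal length")
})

test_that("F84 agrees with ape::dist.dna with pairwise deletion", {
  # two-sequence alignments: pooled-pair and whole-alignment frequency
  # conventions coincide, so this cross-checks the distance formula itself
  # (no missing data here: ape pools frequencies over every site, so the
  # two conventions only coincide exactly when no site is deleted)
  tr <- timetree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 0, 4e6))
  for (seed in 1:4) {
    aln <- simulate_sequences(tr, 1e-8, 8, 99, c(0.34, 0.16, 0.21, 0.29),
                              15000, seed = seed)
    mine <- f84_distance(aln$seqs[[1]], aln$seqs[[2]])
    bin <- ape::as.DNAbin(do.call(rbind,
                                  strsplit(tolower(unlist(aln$seqs)), "")))
    ref <- ape::dist.dna(bin, model = "F84", pairwise.deletion = TRUE)[1]
    expect_equal(as.numeric(mine), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("global-frequency mode matches ape on a multi-sequence alignment", {
  tr <- simulate_coalescent_tree(c(0, 0, 0, 0, 0), 2e6, seed = 41)
  aln <- simulate_sequences(tr, 1e-9, 10, 99, c(0.3, 0.2, 0.22, 0.28),
                            12000, seed = 42)
  D <- distance_matrix(aln, freqs = "global")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(unlist(aln$seqs)), "")))
  Dref <- as.matrix(ape::dist.dna(bin, model = "F84",
                                  pairwise.deletion = TRUE))
  expect_equal(D[, ], unname(Dref), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("equal frequencies reduce F84 to the K80 closed form", {
  tr <- timetree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 0, 3e6))
  aln <- simulate_sequences(tr, 1e-8, 6, 99, rep(0.25, 4), 20000, seed = 43)
  d <- f84_distance(aln$seqs[[1]], aln$seqs[[2]], freqs = "global",
                    global_freqs = rep(0.25, 4))
  a <- strsplit(aln$seqs[[1]], "")[[1]]; b <- strsplit(aln$seqs[[2]], "")[[1]]
  pur <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  P <- mean(a != b & pur[a] == pur[b]); Q <- mean(a != b & pur[a] != pur[b])
  k80 <- 0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
  expect_equal(as.numeric(d), k80, tolerance = 1e-10)
})

test_that("the estimator recovers the simulated divergence", {
  # true divergence 0.05 substitutions/site; mean over replicates within 5%
  t_yr <- 0.05 / (2 * 1e-8)
  tr <- timetree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 0, t_yr))
  # purine and pyrimidine contents of 0.5 each make the HKY simulation an
  # exact F84 submodel, so the estimator is consistent
  d <- vapply(1:60, function(s) {
    aln <- simulate_sequences(tr, 1e-8, 8, 99, c(0.3, 0.2, 0.2, 0.3),
                              8000, seed = 100 + s)
    as.numeric(f84_distance(aln$seqs[[1]], aln$seqs[[2]]))
  }, 0)
  expect_lt(abs(mean(d) - 0.05) / 0.05, 0.05)
})

test_that("saturation is flagged, never clamped", {
  set.seed(45)
  a <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  b <- chartr("ACGT", "GTAC", a)  # every site a transition: log arg <= 0
  d <- f84_distance(a, b)
  expect_true(is.na(d))
  expect_equal(attr(d, "reason"), "saturated")
  # purine-only pair: frequency estimates degenerate, also flagged
  p <- strrep("AG", 100)
  expect_equal(attr(f84_distance(p, chartr("AG", "GA", p)), "reason"),
               "degenerate_freqs")
})

test_that("distance_matrix is symmetric and permutation-equivariant", {
  tr <- simulate_coalescent_tree(c(0, 0, 0, 0), 5e5, seed = 46)
  aln <- simulate_sequences(tr, 1e-8, 8, 0.5, rep(0.25, 4), 5000, seed = 47)
  D <- distance_matrix(aln)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  perm <- c(3, 1, 4, 2)
  Dp <- distance_matrix(dna_alignment(aln$seqs[perm]))
  expect_equal(Dp[, ], D[perm, perm], ignore_attr = TRUE)
  one <- distance_matrix(dna_alignment(aln$seqs[1]))
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(one[1, 1], 0)
  # consistency with three independent pairwise calls
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_equal(D[pair[1], pair[2]],
                 as.numeric(f84_distance(aln$seqs[[pair[1]]],
                                         aln$seqs[[pair[2]]])))
})
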