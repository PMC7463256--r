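test_that("zero rate copies the root draw to every tip", {
  tr <- fixture_tree4()
  aln <- simulate_sequences(tr, 0, 5, 0.5, rep(0.25, 4), 200, seed = 1)
  expect_true(all(aln$seqs == aln$seqs[[1]]))
})

test_that("two-tip divergence matches the JC69 closed form", {
  # kappa = 1, uniform frequencies, no rate variation: p-distance at
  # divergence d follows 3/4 (1 - exp(-4d/3))
  tr <- timetree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 0, 5e6))
  L <- 40000
  aln <- simulate_sequences(tr, 1e-8, 1, 1e6, rep(0.25, 4), L, seed = 8)
  p <- mean(strsplit(aln$seqs[[1]], "")[[1]] != strsplit(aln$seqs[[2]], "")[[1]])
  d <- 2 * 5e6 * 1e-8
  p_exp <- 3 / 4 * (1 - exp(-4 * d / 3))
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / L))
})

test_that("base composition converges to the stationary frequencies", {
  tr <- simulate_coalescent_tree(c(0, 0, 0), 1e5, seed = 2)
  f0 <- c(0.32, 0.26, 0.13, 0.29)
  aln <- simulate_sequences(tr, 1e-8, 4, 0.5, f0, 100000, seed = 3)
  expect_lt(max(abs(empirical_base_freqs(aln) - f0)), 0.01)
})

test_that("site-pattern frequencies match pruning probabilities on 3 taxa", {
  # dual-route check: simulate 1e5 sites on a fixed 3-taxon tree and compare
  # pattern counts against probabilities computed by the likelihood engine
  tr <- timetree(rbind(c(5L, 1L), c(5L, 2L), c(4L, 5L), c(4L, 3L)),
                 c("a", "b", "c"), c(0, 0, 0, 8e6, 3e6))
  m <- fixture_model(rate = 1e-8, kappa = 6, alpha = 0.4,
                     freqs = c(0.3, 0.2, 0.24, 0.26))
  L <- 1e5
  aln <- simulate_sequences(tr, m$rate, m$kappa, m$alpha,
                            unname(m$base_freqs), L, seed = 77)
  obs <- table(factor(paste0(
    strsplit(aln$seqs[["a"]], "")[[1]],
    strsplit(aln$seqs[["b"]], "")[[1]],
    strsplit(aln$seqs[["c"]], "")[[1]]),
    levels = apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                               c("A","C","G","T")), 1, paste, collapse = "")))
  probs <- vapply(names(obs), function(pat) {
    s <- strsplit(pat, "")[[1]]
    exp(log_likelihood(tr, dna_alignment(stats::setNames(s, c("a","b","c"))), m))
  }, 0)
  expect_equal(sum(probs), 1, tolerance = 1e-8)
  gof <- stats::chisq.test(as.numeric(obs), p = probs)
  expect_gt(gof$p.value, 0.01)
})

test_that("missing-data masking hits the requested fraction in runs", {
  tr <- fixture_tree4()
  aln <- simulate_sequences(tr, 1e-9, 5, 0.5, rep(0.25, 4), 20000, seed = 4,
                            missing_frac = 0.15, missing_run_mean = 200)
  fracN <- vapply(aln$seqs, function(s)
    mean(strsplit(s, "")[[1]] == "N"), 0)
  expect_true(all(fracN >= 0.15 & fracN < 0.35))  # runs overshoot modestly
})

test_that("simulation is reproducible and validates input", {
  tr <- fixture_tree4()
  a <- simulate_sequences(tr, 1e-8, 5, 0.5, rep(0.25, 4), 100, seed = 9)
  b <- simulate_sequences(tr, 1e-8, 5, 0.5, rep(0.25, 4), 100, seed = 9)
  expect_identical(a$seqs, b$seqs)
  expect_error(simulate_sequences(tr, 1e-8, 5, 0.5, c(0.5, 0.5, 0.5, 0.5),
                                  100, seed = 1), "simplex")
  expect_error(simulate_sequences(tr, 1e-8, 5, 0.5, rep(0.25, 4), 100),
               "seed")
})
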