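test_that("two-tip TMRCA is exponential with mean pop_size", {
  N <- 1000
  tm <- vapply(1:4000, function(i)
    root_age(simulate_coalescent_tree(c(0, 0), N, seed = i)), 0)
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - N), 3 * se)
})

test_that("serial sampling shifts the coalescent window", {
  # tips at 0 and 5N: TMRCA always > 5N, excess exponential with mean N
  N <- 500
  tm <- vapply(1:4000, function(i)
    root_age(simulate_coalescent_tree(c(0, 5 * N), N, seed = i)), 0)
  expect_true(all(tm > 5 * N))
  excess <- tm - 5 * N
  se <- stats::sd(excess) / sqrt(length(excess))
  expect_lt(abs(mean(excess) - N), 3 * se)
})

test_that("coalescent simulator rejects invalid input", {
  expect_error(simulate_coalescent_tree(c(0), 10, seed = 1), "2 tips")
  expect_error(simulate_coalescent_tree(c(0, 0), -1, seed = 1), "pop_size")
  expect_error(simulate_coalescent_tree(c(0, NA), 10, seed = 1), "finite")
})

test_that("simulated trees are valid serial-sample genealogies", {
  tr <- simulate_coalescent_tree(c(0, 100, 250, 250, 900), 300, seed = 99)
  expect_s3_class(tr, "timetree")  # constructor runs full validation
  expect_equal(unname(tip_ages(tr)), c(0, 100, 250, 250, 900))
  expect_identical(simulate_coalescent_tree(c(0, 100, 250), 300, seed = 5),
                   simulate_coalescent_tree(c(0, 100, 250), 300, seed = 5))
})

test_that("two-tip coalescent density matches the closed form", {
  # isochronous: log f = -log N - t/N
  tr <- timetree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 0, 42))
  N <- 17
  expect_equal(coalescent_log_density(tr, N), -log(N) - 42 / N, tolerance = 1e-12)
  # serial tips at 0 and s: log f = -log N - (t - s)/N
  trs <- timetree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 30, 42))
  expect_equal(coalescent_log_density(trs, N), -log(N) - 12 / N, tolerance = 1e-12)
})

test_that("coalescent density agrees with a Monte-Carlo histogram on 3 tips", {
  # simulate many 3-tip genealogies, bin the (first, second) coalescence
  # times, and compare bin probabilities against the density integrated by
  # midpoint over each bin
  N <- 100
  tips <- c(0, 0, 0)
  reps <- 8000
  sims <- t(vapply(1:reps, function(i) {
    tr <- simulate_coalescent_tree(tips, N, seed = 20000 + i)
    sort(tr$ages[4:5])
  }, c(0, 0)))
  brk <- c(0, 40, 90, 160)
  for (bi in 1:3) for (bj in 1:3) {
    lo1 <- brk[bi]; hi1 <- brk[bi + 1]; lo2 <- brk[bj]; hi2 <- brk[bj + 1]
    p_obs <- mean(sims[, 1] >= lo1 & sims[, 1] < hi1 &
                  sims[, 2] >= lo2 & sims[, 2] < hi2)
    # midpoint quadrature of the closed-form density over the bin
    g1 <- seq(lo1 + (hi1 - lo1) / 40, hi1, length.out = 20)
    g2 <- seq(lo2 + (hi2 - lo2) / 40, hi2, length.out = 20)
    p_exp <- 0
    for (u in g1) for (v in g2) {
      if (v <= u) next
      tr <- timetree(rbind(c(5L, 1L), c(5L, 2L), c(4L, 5L), c(4L, 3L)),
                     c("a", "b", "c"), c(0, 0, 0, v, u))
      # 3 labelled topologies share the same density; first-coal pair is
      # unordered so multiply by the 3 ways the pair can be chosen
      p_exp <- p_exp + 3 * exp(coalescent_log_density(tr, N)) *
        (hi1 - lo1) / 20 * (hi2 - lo2) / 20
    }
    se <- sqrt(p_exp * (1 - p_exp) / reps)
    expect_lt(abs(p_obs - p_exp), 4 * se + 0.01)
  }
})

test_that("density decreases toward -log(2N) when doubling pop_size", {
  tr <- timetree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 0, 1))
  N <- seq(10, 1e4, length.out = 50)
  ld <- vapply(N, function(x) coalescent_log_density(tr, x), 0)
  expect_true(all(diff(ld) < 0))  # short TMRCA: density falls as N grows
  expect_equal(ld, -log(N) - 1 / N, tolerance = 1e-12)
})
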