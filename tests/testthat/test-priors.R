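test_that("tip_date_spec applies study defaults and validates", {
  tab <- data.frame(id = c("young", "old"), status = c("fixed", "estimated"),
                    age_bp = c(13000, NA))
  spec <- tip_date_spec(tab)
  expect_equal(spec$reference_age, 13000)
  row <- spec$table[spec$table$id == "old", ]
  expect_equal(c(row$lower_bp, row$upper_bp, row$prior_shape, row$prior_scale),
               c(50000, 800000, 1, 200000))
  expect_error(tip_date_spec(data.frame(id = "a", status = "estimated",
                                        age_bp = NA)),
               "fixed-age")
  expect_error(tip_date_spec(data.frame(id = c("a", "b"),
                                        status = c("fixed", "estimated"),
                                        age_bp = c(1000, NA),
                                        lower_bp = 5e5, upper_bp = 4e5)),
               "lower_bp")
  # offset interpretation shifts the bounds by the reference age
  spec2 <- tip_date_spec(data.frame(id = c("young", "old"),
                                    status = c("fixed", "estimated"),
                                    age_bp = c(13000, NA),
                                    lower_bp = 0, upper_bp = 787000),
                         bounds_scale = "offset")
  row2 <- spec2$table[spec2$table$id == "old", ]
  expect_equal(c(row2$lower_bp, row2$upper_bp), c(13000, 800000))
})

test_that("the truncated gamma tip prior is a normalised density", {
  tab <- data.frame(id = c("young", "old"), status = c("fixed", "estimated"),
                    age_bp = c(13000, NA))
  spec <- tip_date_spec(tab)
  # integrate exp(log prior) over the relative-age support
  f <- Vectorize(function(a) exp(tipdater:::tip_log_prior(spec, "old", a)))
  total <- stats::integrate(f, 50000 - 13000, 800000 - 13000,
                            rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_identical(tipdater:::tip_log_prior(spec, "old", 36000), -Inf)
  expect_identical(tipdater:::tip_log_prior(spec, "old", 790000), -Inf)
})

test_that("fit_prior recovers a flat density on its support", {
  set.seed(61)
  x <- stats::runif(5000, 10, 30)
  ps <- fit_prior(x, 10, 30)
  grid <- seq(12, 28, length.out = 50)  # central 80%
  dens <- exp(prior_log_density(ps, grid))
  expect_true(all(abs(dens - 1 / 20) / (1 / 20) < 0.10))
  expect_identical(prior_log_density(ps, 9), -Inf)
  expect_identical(prior_log_density(ps, 31), -Inf)
})

test_that("fit_prior integrates to one and preserves moments", {
  set.seed(62)
  x <- stats::qexp(stats::runif(4000, 0, stats::pexp(3)))  # Exp truncated at 3
  ps <- fit_prior(x, 0, 3)
  g <- ps$grid
  total <- sum((ps$density[-1] + ps$density[-length(g)]) / 2) * diff(g)[1]
  expect_equal(total, 1, tolerance = 1e-3)
  mu <- sum(g * ps$density) * diff(g)[1]
  expect_lt(abs(mu - mean(x)) / mean(x), 0.05)
})

test_that("fit_prior handles degenerate and invalid input", {
  expect_error(fit_prior(1:50, 0, 100), "at least 100")
  expect_error(fit_prior(stats::runif(200, 5, 6), 0, 1), "outside")
  near_point <- fit_prior(rep(0.5, 200), 0, 1)
  total <- sum((near_point$density[-1] + near_point$density[-512]) / 2) *
    diff(near_point$grid)[1]
  expect_equal(total, 1, tolerance = 1e-3)
  # mass concentrated near the point
  expect_gt(mean(exp(prior_log_density(near_point, c(0.49, 0.5, 0.51)))),
            exp(prior_log_density(near_point, 0.1)))
})

test_that("clock priors validate their bounds", {
  cp <- clock_priors()
  expect_equal(c(cp$rate_min, cp$rate_max), c(4e-10, 8e-8))
  expect_equal(c(cp$pop_min, cp$pop_max), c(1, 1e6))
  expect_error(clock_priors(rate_min = 1e-8, rate_max = 1e-9), "ordered")
})
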