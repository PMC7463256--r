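#' Per-tip dating specification
#'
#' Describes, for every tip, whether its sampling age is fixed (a calibrated
#' point value in years BP) or to be estimated. Estimated tips carry a gamma
#' prior (default shape 1, scale 200,000 years — an exponential with mean
#' 200 ky) truncated and renormalised to hard bounds, by default 50 ky (the
#' approximate limit of radiocarbon dating) and 800 ky (the approximate limit
#' of ancient-DNA recovery). Bounds and ages are stated in years BP;
#' internally everything is handled relative to the youngest fixed tip
#' (`reference_age`, e.g. 13 ky BP), whose age defines time zero of the tree.
#'
#' @param tips data frame with columns `id`, `status` (`"fixed"` or
#'   `"estimated"`), `age_bp` (required for fixed tips), and optionally
#'   `lower_bp`, `upper_bp`, `prior_shape`, `prior_scale` (recycled defaults
#'   50000, 800000, 1, 200000).
#' @param bounds_scale `"absolute"` if `lower_bp`/`upper_bp` are absolute
#'   years BP (default), `"offset"` if they are offsets from the reference
#'   age.
#' @return an object of class `tip_date_spec`.
#' @export
tip_date_spec <- function(tips, bounds_scale = c("absolute", "offset")) {
  bounds_scale <- match.arg(bounds_scale)
  stopifnot(is.data.frame(tips), all(c("id", "status") %in% names(tips)))
  if (!all(tips$status %in% c("fixed", "estimated")))
    stop("status must be 'fixed' or 'estimated'", call. = FALSE)
  if (anyDuplicated(tips$id)) stop("duplicate tip ids", call. = FALSE)
  if (!any(tips$status == "fixed"))
    stop("at least one fixed-age tip is required to anchor the timescale",
         call. = FALSE)
  n <- nrow(tips)
  if (is.null(tips$lower_bp)) tips$lower_bp <- rep(50000, n)
  if (is.null(tips$upper_bp)) tips$upper_bp <- rep(800000, n)
  if (is.null(tips$prior_shape)) tips$prior_shape <- rep(1, n)
  if (is.null(tips$prior_scale)) tips$prior_scale <- rep(200000, n)
  tips$lower_bp[is.na(tips$lower_bp)] <- 50000
  tips$upper_bp[is.na(tips$upper_bp)] <- 800000
  tips$prior_shape[is.na(tips$prior_shape)] <- 1
  tips$prior_scale[is.na(tips$prior_scale)] <- 200000

  fixed <- tips$status == "fixed"
  if (any(fixed & !is.finite(tips$age_bp)))
    stop("fixed tips must have a finite age_bp", call. = FALSE)
  reference_age <- min(tips$age_bp[fixed])
  if (bounds_scale == "offset") {
    tips$lower_bp <- tips$lower_bp + reference_age
    tips$upper_bp <- tips$upper_bp + reference_age
  }
  est <- !fixed
  if (any(est & tips$lower_bp >= tips$upper_bp))
    stop("lower_bp must be < upper_bp for estimated tips", call. = FALSE)
  if (any(est & tips$lower_bp < reference_age))
    tips$lower_bp[est] <- pmax(tips$lower_bp[est], reference_age)

  structure(
    list(table = tips, reference_age = reference_age,
         bounds_scale = bounds_scale),
    class = "tip_date_spec"
  )
}

#' @export
print.tip_date_spec <- function(x, ...) {
  cat("tip_date_spec:", sum(x$table$status == "fixed"), "fixed,",
      sum(x$table$status == "estimated"), "estimated tips;",
      "reference age", x$reference_age, "yr BP\n")
  invisible(x)
}

## relative (tree-scale) ages of the fixed tips, named by id
fixed_rel_ages <- function(spec) {
  f <- spec$table[spec$table$status == "fixed", ]
  stats::setNames(f$age_bp - spec$reference_age, f$id)
}

estimated_ids <- function(spec) {
  spec$table$id[spec$table$status == "estimated"]
}

## per-tip truncated-gamma log prior, evaluated at a relative (tree-scale)
## age; the gamma density and bounds live on the BP scale
tip_log_prior <- function(spec, id, age_rel, override = NULL) {
  row <- spec$table[spec$table$id == id, ]
  y <- age_rel + spec$reference_age
  if (y < row$lower_bp || y > row$upper_bp) return(-Inf)
  if (!is.null(override)) return(prior_log_density(override, y))
  stats::dgamma(y, shape = row$prior_shape, scale = row$prior_scale, log = TRUE) -
    log(stats::pgamma(row$upper_bp, row$prior_shape, scale = row$prior_scale) -
        stats::pgamma(row$lower_bp, row$prior_shape, scale = row$prior_scale))
}

#' Clock and population-size priors
#'
#' Uniform priors on the strict-clock substitution rate and the coalescent
#' population-size parameter. Defaults are `Uniform[4e-10, 8e-8]`
#' substitutions/site/year for the rate and `Uniform[1, 1e6]` (years) for the
#' population size.
#'
#' @param rate_min,rate_max rate prior bounds (subs/site/year).
#' @param pop_min,pop_max population-size prior bounds (years).
#' @return an object of class `clock_priors`.
#' @export
clock_priors <- function(rate_min = 4e-10, rate_max = 8e-8,
                         pop_min = 1, pop_max = 1e6) {
  if (rate_min <= 0 || rate_min >= rate_max || pop_min <= 0 || pop_min >= pop_max)
    stop("prior bounds must be positive and ordered", call. = FALSE)
  structure(list(rate_min = rate_min, rate_max = rate_max,
                 pop_min = pop_min, pop_max = pop_max),
            class = "clock_priors")
}

#' Fit a reusable prior density to posterior samples
#'
#' Encodes a marginal posterior sample as a normalised density on a bounded
#' support, for use as the tip-age prior of a later analysis (the second
#' stage of the individually-dated procedure). The estimate is a
#' boundary-reflected Gaussian kernel density: mass that the kernel would
#' place outside `[lower, upper]` is folded back in, so hard bounds do not
#' produce edge bias, and the result is renormalised to integrate to 1.
#'
#' @param samples numeric vector of at least 100 draws within the support.
#' @param lower,upper support bounds.
#' @param n_grid grid resolution (default 512).
#' @return an object of class `prior_spec` whose log-density is evaluated
#'   with [prior_log_density].
#' @export
fit_prior <- function(samples, lower, upper, n_grid = 512L) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100L)
    stop("need at least 100 samples to fit a prior", call. = FALSE)
  if (any(samples < lower - 1e-9 * (upper - lower)) ||
      any(samples > upper + 1e-9 * (upper - lower)))
    stop("samples fall outside [lower, upper]", call. = FALSE)
  bw <- stats::bw.nrd0(samples)
  if (!is.finite(bw) || bw <= 0) bw <- max((upper - lower) * 1e-4, 1e-12)
  if (length(samples) > 5000L)  # grid evaluation is O(grid x samples)
    samples <- samples[seq(1L, length(samples), length.out = 5000L)]
  grid <- seq(lower, upper, length.out = n_grid)
  dens <- function(x) {
    rowMeans(stats::dnorm(outer(x, samples, "-"), sd = bw))
  }
  f <- dens(grid) + dens(2 * lower - grid) + dens(2 * upper - grid)
  dx <- grid[2L] - grid[1L]
  total <- sum((f[-1L] + f[-n_grid]) / 2) * dx  # trapezoid
  f <- f / total
  structure(list(grid = grid, density = f, lower = lower, upper = upper,
                 bw = bw, n_samples = length(samples)),
            class = "prior_spec")
}

#' Evaluate the log-density of a fitted prior
#'
#' @param spec a `prior_spec` from [fit_prior].
#' @param x numeric vector of evaluation points.
#' @return log-density values; `-Inf` outside the support.
#' @export
prior_log_density <- function(spec, x) {
  out <- rep(-Inf, length(x))
  inside <- x >= spec$lower & x <= spec$upper
  if (any(inside)) {
    f <- stats::approx(spec$grid, spec$density, xout = x[inside])$y
    f[!is.finite(f) | f <= 0] <- 1e-300
    out[inside] <- log(f)
  }
  out
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("prior_spec on [", format(x$lower), ",", format(x$upper), "] fitted to",
      x$n_samples, "samples (bw", format(x$bw), ")\n")
  invisible(x)
}
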