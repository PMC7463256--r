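#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples. Ties between equally short windows are broken toward the
#' lower start.
#'
#' @param samples numeric vector of posterior draws.
#' @param mass interval mass in (0, 1), default 0.95.
#' @return numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n == 0L) stop("no samples", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1L], s[n]))
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)  # which.min takes the first (lowest) minimiser
  c(s[i], s[i + m - 1L])
}

#' Effective sample size from autocorrelation time
#'
#' `n / tau` with integrated autocorrelation time `tau` estimated by Geyer's
#' initial positive sequence: sums of consecutive autocorrelation pairs are
#' accumulated until the first non-positive pair.
#'
#' @param x numeric vector (one MCMC trace column).
#' @return the effective sample size; `NA` for constant input.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(NA_real_)
  lag_max <- min(n - 2L, 2000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[, 1L, 1L]
  tau <- -1
  m <- 0L
  while (2L * m + 1L <= lag_max) {
    g <- rho[2L * m + 1L] + rho[2L * m + 2L]  # rho[k+1] is lag k
    if (!is.finite(g) || g <= 0) break
    tau <- tau + 2 * g
    m <- m + 1L
  }
  tau <- max(tau, 1)
  min(n / tau, n)
}

## histogram/KDE mode of a sample
sample_mode <- function(x) {
  if (stats::sd(x) == 0) return(x[1L])
  d <- stats::density(x, n = 512L)
  d$x[which.max(d$y)]
}

#' Summarise an MCMC trace
#'
#' Median, 95% HPD interval, autocorrelation-based effective sample size and
#' histogram mode for each tracked parameter. Parameters with ESS below 200
#' (or a constant trace) trigger a warning, since their summaries are not
#' trustworthy.
#'
#' @param trace an `mcmc_trace` (see [mcmc_run]) or a data frame of samples.
#' @param targets parameter (column) names to summarise; defaults to every
#'   parameter column (step and log-density bookkeeping columns excluded).
#' @param mass HPD mass (default 0.95).
#' @return a data frame with one row per parameter: `parameter`, `median`,
#'   `hpd_low`, `hpd_high`, `ess`, `mode`.
#' @export
summarize_trace <- function(trace, targets = NULL, mass = 0.95) {
  df <- as.data.frame(trace)
  if (nrow(df) == 0L) stop("empty trace", call. = FALSE)
  if (is.null(targets))
    targets <- setdiff(names(df), c("step", "posterior", "likelihood",
                                    "prior", "chain"))
  out <- do.call(rbind, lapply(targets, function(p) {
    x <- df[[p]]
    hpd <- hpd_interval(x, mass)
    data.frame(parameter = p, median = stats::median(x),
               hpd_low = hpd[1L], hpd_high = hpd[2L],
               ess = effective_sample_size(x), mode = sample_mode(x),
               stringsAsFactors = FALSE)
  }))
  low <- is.na(out$ess) | out$ess < 200
  if (any(low))
    warning("ESS < 200 for: ", paste(out$parameter[low], collapse = ", "),
            call. = FALSE)
  rownames(out) <- NULL
  out
}
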