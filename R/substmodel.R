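BASES <- c("A", "C", "G", "T")

#' HKY+G substitution model
#'
#' Bundles the parameters of a Hasegawa-Kishino-Yano model with discrete-gamma
#' among-site rate variation and a strict molecular clock: the
#' transition/transversion rate ratio `kappa`, the stationary base frequencies,
#' the gamma shape `alpha` (with `n_categories` equal-probability categories),
#' and the clock rate in substitutions/site/year. The rate matrix is
#' normalised to one expected substitution per site per unit of
#' `rate * time`, so the clock rate is directly interpretable.
#'
#' The spectral decomposition of the (reversible) rate matrix is precomputed
#' once here, so transition probabilities for any branch length are a fixed
#' small matrix product.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param base_freqs numeric length-4 simplex over A, C, G, T.
#' @param alpha gamma shape for among-site rate variation (> 0).
#' @param rate clock rate in substitutions/site/year (> 0).
#' @param n_categories number of discrete-gamma categories (default 4).
#' @return an object of class `subst_model`.
#' @export
subst_model <- function(kappa, base_freqs, alpha, rate, n_categories = 4L) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  base_freqs <- as.numeric(base_freqs)
  if (length(base_freqs) != 4L || any(base_freqs <= 0) ||
      abs(sum(base_freqs) - 1) > 1e-12)
    stop("base_freqs must be a length-4 simplex summing to 1", call. = FALSE)
  Q <- hky_q_matrix(kappa, base_freqs)
  eig <- rev_eigen(Q, base_freqs)
  structure(
    list(kappa = kappa, base_freqs = stats::setNames(base_freqs, BASES),
         alpha = alpha, rate = rate, n_categories = as.integer(n_categories),
         category_rates = gamma_category_rates(alpha, n_categories),
         Q = Q, evals = eig$values, U = eig$U, Uinv = eig$Uinv),
    class = "subst_model"
  )
}

#' @export
print.subst_model <- function(x, ...) {
  cat("HKY+G", x$n_categories, " substitution model\n", sep = "")
  cat("  kappa:", x$kappa, " alpha:", x$alpha,
      " rate:", format(x$rate), "subs/site/yr\n")
  cat("  base freqs:", paste(sprintf("%s=%.4f", BASES, x$base_freqs),
                             collapse = " "), "\n")
  invisible(x)
}

## HKY rate matrix, normalised to one expected substitution per unit distance
hky_q_matrix <- function(kappa, freqs) {
  Q <- matrix(rep(freqs, each = 4L), 4L, 4L)
  transitions <- rbind(c(1L, 3L), c(3L, 1L), c(2L, 4L), c(4L, 2L))  # A<->G, C<->T
  Q[transitions] <- Q[transitions] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

## spectral decomposition of a reversible rate matrix via symmetrisation:
## S = D^{1/2} Q D^{-1/2} is symmetric, so Q = U diag(values) Uinv with
## U = D^{-1/2} V, Uinv = V' D^{1/2}
rev_eigen <- function(Q, freqs) {
  d <- sqrt(freqs)
  S <- (Q * rep(d, times = 4L)) * rep(1 / d, each = 4L)
  S <- (S + t(S)) / 2  # symmetrise away rounding noise
  es <- eigen(S, symmetric = TRUE)
  list(values = es$values,
       U = es$vectors / d,
       Uinv = t(es$vectors) * rep(d, each = 4L))
}

#' Discrete-gamma category rates
#'
#' Equal-probability categories with rates at the quantile medians of a
#' gamma(shape = alpha, rate = alpha) distribution, rescaled to mean one.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories.
#' @return numeric vector of `k` mean-one rate multipliers.
#' @export
gamma_category_rates <- function(alpha, k = 4L) {
  r <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k), shape = alpha, rate = alpha)
  r / mean(r)
}

#' HKY transition-probability matrix
#'
#' Closed-form transition probabilities over an elapsed time, for one
#' discrete-gamma category. The expected number of substitutions on the branch
#' is `rate * category_rate * elapsed_years`.
#'
#' @param model a [subst_model].
#' @param elapsed_years elapsed time in years (>= 0).
#' @param category_rate rate multiplier of the gamma category (default 1).
#' @return a 4x4 row-stochastic matrix over A, C, G, T.
#' @export
hky_transition_matrix <- function(model, elapsed_years, category_rate = 1) {
  if (!is.finite(elapsed_years) || elapsed_years < 0)
    stop("elapsed time must be >= 0", call. = FALSE)
  d <- model$rate * category_rate * elapsed_years
  P <- model$U %*% (exp(model$evals * d) * model$Uinv)
  P[P < 0] <- 0  # clip eigen rounding noise at very small/large distances
  dimnames(P) <- list(BASES, BASES)
  P
}
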