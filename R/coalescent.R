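#' Simulate a heterochronous constant-size coalescent genealogy
#'
#' Draws a rooted binary genealogy for serially sampled tips under the
#' constant-population-size coalescent. Going backwards in time, while `k`
#' lineages are active the waiting time to the next coalescence is exponential
#' with rate `k (k - 1) / (2 pop_size)`; the clock restarts whenever a new tip
#' enters as its sampling time is passed. `pop_size` is the product of the
#' effective population size and the generation time, so it is expressed in
#' years — the same timescale as the tip ages.
#'
#' @param tip_ages numeric vector of sampling times in years before the
#'   youngest tip (>= 0); length >= 2.
#' @param pop_size coalescent population-size parameter, in years (> 0).
#' @param seed integer seed (mandatory, for reproducibility).
#' @param labels optional tip labels; defaults to `t1, t2, ...` in the order
#'   of `tip_ages`.
#' @return a [timetree].
#' @export
simulate_coalescent_tree <- function(tip_ages, pop_size, seed, labels = NULL) {
  n <- length(tip_ages)
  if (n < 2L) stop("need at least 2 tips", call. = FALSE)
  if (!is.finite(pop_size) || pop_size <= 0) stop("pop_size must be > 0", call. = FALSE)
  if (any(!is.finite(tip_ages)) || any(tip_ages < 0))
    stop("tip_ages must be finite and >= 0", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  set.seed(as.integer(seed))

  ord <- order(tip_ages)
  n_node <- 2L * n - 1L
  ages <- numeric(n_node)
  ages[seq_len(n)] <- tip_ages
  edge_parent <- integer(n_node - 1L)
  edge_child <- integer(n_node - 1L)
  n_edge <- 0L

  active <- integer(0)
  i <- 1L                       # next tip (by age) to activate
  nxt <- n + 1L                 # next internal node id (provisional numbering)
  t <- tip_ages[ord[i]]
  repeat {
    # activate all tips sampled at exactly time t
    while (i <= n && tip_ages[ord[i]] <= t) {
      active <- c(active, ord[i]); i <- i + 1L
    }
    k <- length(active)
    t_sample <- if (i <= n) tip_ages[ord[i]] else Inf
    if (k >= 2L) {
      wait <- stats::rexp(1L, rate = k * (k - 1L) / (2 * pop_size))
      t_co <- t + wait
    } else {
      t_co <- Inf
    }
    if (t_co <= t_sample) {
      pair <- sample(k, 2L)
      a <- active[pair[1L]]; b <- active[pair[2L]]
      ages[nxt] <- t_co
      edge_parent[n_edge + 1L] <- nxt; edge_child[n_edge + 1L] <- a
      edge_parent[n_edge + 2L] <- nxt; edge_child[n_edge + 2L] <- b
      n_edge <- n_edge + 2L
      active <- c(active[-pair], nxt)
      nxt <- nxt + 1L
      t <- t_co
      if (length(active) == 1L && i > n) break
    } else {
      t <- t_sample
    }
  }
  # provisional numbering gives the root id 2n-1; ape wants the root at n+1.
  # Rotate internal ids: root -> n+1, every other internal node shifts up by 1.
  remap <- function(v) ifelse(v == n_node, n + 1L, ifelse(v > n, v + 1L, v))
  ages_new <- ages
  ages_new[remap((n + 1L):n_node)] <- ages[(n + 1L):n_node]
  timetree(cbind(remap(edge_parent), remap(edge_child)), labels, ages_new)
}

#' Log-density of a genealogy under the serial-sample constant-size coalescent
#'
#' Each inter-event interval with `k` active lineages and duration `dt`
#' contributes `-k (k - 1) dt / (2 pop_size)`; each coalescence contributes an
#' additional `-log(pop_size)`. Tips entering at their sampling times restart
#' the lineage count. At tied event times, sampling events are processed
#' before coalescences.
#'
#' @param tree a [timetree].
#' @param pop_size population-size parameter in years (> 0).
#' @return the log-density (log scale, natural log). `-Inf` is never returned
#'   for a structurally valid `timetree`; invalid input errors instead.
#' @export
coalescent_log_density <- function(tree, pop_size) {
  if (!inherits(tree, "timetree")) stop("tree must be a timetree", call. = FALSE)
  if (!is.finite(pop_size) || pop_size <= 0) stop("pop_size must be > 0", call. = FALSE)
  coalescent_log_density_ages(tree$ages[seq_len(tree$n_tip)],
                              tree$ages[(tree$n_tip + 1L):(2L * tree$n_tip - 1L)],
                              pop_size)
}

## the same density from raw age vectors; the MCMC inner loop calls the
## compiled kernel directly (building a timetree per step would dominate)
coalescent_log_density_ages <- function(tip_ages, coal_ages, pop_size) {
  coal_log_density_cpp(tip_ages, coal_ages, pop_size)
}
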