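#' MCMC configuration
#'
#' Settings for the Metropolis-Hastings sampler: chain length, thinning,
#' burn-in fraction, the relative proposal weight of tip-age moves (the
#' study design uses 5, so unknown specimen ages are sampled more often),
#' whether narrow-exchange topology moves are enabled (by default the
#' topology is fixed and only node ages move), the number of replicate
#' chains, and the seed.
#'
#' @param chain_length total number of MCMC steps; must be divisible by
#'   `sample_every`.
#' @param sample_every thinning interval in steps.
#' @param burnin_fraction fraction of each chain discarded (default 0.1).
#' @param tip_move_weight relative proposal weight of each estimated tip age
#'   (default 5).
#' @param topology_moves enable narrow-exchange topology moves (default
#'   `FALSE`).
#' @param n_replicates number of replicate chains for [joint_dating] /
#'   [individual_dating] (default 2).
#' @param seed integer seed (mandatory).
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length, sample_every, burnin_fraction = 0.1,
                        tip_move_weight = 5, topology_moves = FALSE,
                        n_replicates = 2L, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  chain_length <- as.integer(chain_length)
  sample_every <- as.integer(sample_every)
  if (chain_length %% sample_every != 0L)
    stop("chain_length must be divisible by sample_every", call. = FALSE)
  if (tip_move_weight <= 0) stop("weights must be positive", call. = FALSE)
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop("burnin_fraction must be in [0, 1)", call. = FALSE)
  structure(list(chain_length = chain_length, sample_every = sample_every,
                 burnin_fraction = burnin_fraction,
                 tip_move_weight = tip_move_weight,
                 topology_moves = isTRUE(topology_moves),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Log-posterior of a dated-tree state
#'
#' The sum of the pruning log-likelihood, the constant-size coalescent
#' log-density of the genealogy, the truncated-gamma (or refitted) log-priors
#' of the estimated tip ages, and the uniform log-priors on the clock rate
#' and population size. Returns `-Inf` whenever any parameter is outside its
#' prior support; the components are attached as the `"components"`
#' attribute.
#'
#' @param state list with elements `tree` (a [timetree] whose tip ages match
#'   the fixed ages and current estimated ages), `rate`, `pop_size`.
#' @param alignment a [dna_alignment] (may have zero sites, in which case
#'   the likelihood term is 0 and the posterior is the prior).
#' @param tip_spec a [tip_date_spec].
#' @param priors a [clock_priors].
#' @param model a [subst_model] (its `rate` is overridden by `state$rate`).
#' @param tip_prior_overrides optional named list of [fit_prior] objects
#'   replacing the gamma priors of specific estimated tips.
#' @return the log-posterior.
#' @export
log_posterior <- function(state, alignment, tip_spec, priors, model,
                          tip_prior_overrides = NULL) {
  tree <- state$tree
  rate <- state$rate
  pop <- state$pop_size
  lp_clock <- if (rate < priors$rate_min || rate > priors$rate_max) -Inf
              else -log(priors$rate_max - priors$rate_min)
  lp_pop <- if (pop < priors$pop_min || pop > priors$pop_max) -Inf
            else -log(priors$pop_max - priors$pop_min)
  lp_coal <- if (is.finite(lp_pop)) coalescent_log_density(tree, pop) else -Inf
  lp_tips <- 0
  for (id in estimated_ids(tip_spec)) {
    if (!id %in% tree$tip_labels) next
    a <- tree$ages[match(id, tree$tip_labels)]
    lp_tips <- lp_tips + tip_log_prior(tip_spec, id, a,
                                       override = tip_prior_overrides[[id]])
  }
  comp <- c(clock_rate = lp_clock, pop_size = lp_pop, coalescent = lp_coal,
            tip_ages = lp_tips)
  ll <- if (all(is.finite(comp)) && alignment$n_sites > 0L) {
    m <- model; m$rate <- rate
    log_likelihood(tree, alignment, m)
  } else 0
  comp <- c(comp, likelihood = ll)
  structure(sum(comp), components = comp)
}

#' Run a Metropolis-Hastings chain over rate, population size and ages
#'
#' Samples the posterior of a strict-clock HKY+G4 constant-size-coalescent
#' model with fixed and estimated tip ages. Moves: multiplicative scale moves
#' on the clock rate and population size; uniform node-age moves constrained
#' between each internal node's oldest child and its parent; a reflected
#' random walk on the root age; reflected random-walk moves on each estimated
#' tip age within its prior bounds (proposed with relative weight
#' `tip_move_weight`); and optional narrow-exchange topology moves. Proposal
#' scales are auto-tuned toward a 5-80% acceptance window during burn-in
#' only, then frozen to preserve detailed balance.
#'
#' The pruning likelihood is evaluated by a cached engine that only
#' recomputes the conditional likelihoods of nodes whose subtending branches
#' changed, so tip- and node-age moves cost a root path rather than a full
#' tree traversal.
#'
#' @inheritParams log_posterior
#' @param start_tree a [timetree] giving the topology and starting internal
#'   ages; its tips must match `tip_spec`.
#' @param config an [mcmc_config].
#' @param init optional list with starting `rate` and `pop_size`.
#' @param track_nodes optional named list of tip-label vectors; the age of
#'   each set's MRCA is recorded in the trace as `age_node_<name>`.
#' @param replicate replicate index (offsets the seed so duplicate chains
#'   differ).
#' @return an `mcmc_trace` data frame of post-burn-in samples: `step`,
#'   `posterior`, `likelihood`, `prior`, `rate`, `pop_size`, one
#'   `age_<tip>` column per estimated tip and one `age_node_<name>` column
#'   per tracked node (ages in years BP). Acceptance rates and final proposal
#'   scales are in attributes `"acceptance"` and `"scales"`.
#' @export
mcmc_run <- function(alignment, start_tree, tip_spec, priors, model, config,
                     init = NULL, tip_prior_overrides = NULL,
                     track_nodes = NULL, replicate = 1L) {
  stopifnot(inherits(start_tree, "timetree"), inherits(tip_spec, "tip_date_spec"),
            inherits(priors, "clock_priors"), inherits(config, "mcmc_config"))
  n <- start_tree$n_tip
  n_node <- 2L * n - 1L
  labels <- start_tree$tip_labels
  if (!setequal(labels, tip_spec$table$id))
    stop("tree tips and tip_spec ids differ", call. = FALSE)
  set.seed(config$seed + (as.integer(replicate) - 1L) * 1000L)

  ref_age <- tip_spec$reference_age
  est_ids <- intersect(estimated_ids(tip_spec), labels)
  est_idx <- match(est_ids, labels)
  spec_row <- function(id) tip_spec$table[tip_spec$table$id == id, ]
  est_lb <- vapply(est_ids, function(id) spec_row(id)$lower_bp, 0) - ref_age
  est_ub <- vapply(est_ids, function(id) spec_row(id)$upper_bp, 0) - ref_age
  est_shape <- vapply(est_ids, function(id) spec_row(id)$prior_shape, 0)
  est_scale <- vapply(est_ids, function(id) spec_row(id)$prior_scale, 0)
  est_lognorm <- log(stats::pgamma(est_ub + ref_age, est_shape, scale = est_scale) -
                     stats::pgamma(est_lb + ref_age, est_shape, scale = est_scale))
  overrides <- lapply(est_ids, function(id) tip_prior_overrides[[id]])
  names(overrides) <- est_ids

  ## --- initial state -------------------------------------------------------
  edge <- start_tree$edge
  ages <- start_tree$ages
  fixed <- fixed_rel_ages(tip_spec)
  ages[match(names(fixed), labels)] <- fixed
  if (length(est_ids)) {
    pmid <- (stats::pgamma(est_lb + ref_age, est_shape, scale = est_scale) +
             stats::pgamma(est_ub + ref_age, est_shape, scale = est_scale)) / 2
    ages[est_idx] <- stats::qgamma(pmid, est_shape, scale = est_scale) - ref_age
  }
  par <- integer(n_node); par[edge[, 2L]] <- edge[, 1L]
  chl <- matrix(0L, n_node, 2L)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]
    chl[p, if (chl[p, 1L] == 0L) 1L else 2L] <- edge[e, 2L]
  }
  # repair internal ages so every parent is older than its children
  post_ord <- order(start_tree$ages[(n + 1L):n_node]) + n
  for (v in post_ord) {
    lo <- max(ages[chl[v, ]])
    if (ages[v] <= lo) ages[v] <- lo + max(1, 0.01 * abs(lo))
  }
  rate <- if (!is.null(init$rate)) init$rate
          else sqrt(priors$rate_min * priors$rate_max)
  pop <- if (!is.null(init$pop_size)) init$pop_size
         else sqrt(priors$pop_min * priors$pop_max)

  ## --- likelihood engine ---------------------------------------------------
  codes <- aln_codes(alignment)[labels, , drop = FALSE]
  pat <- compress_patterns(codes)
  use_lik <- length(pat$weights) > 0L
  eng <- if (use_lik) plik_init(pat$patterns, pat$weights, model$n_categories)
  U <- model$U; Uinv <- model$Uinv; evals <- model$evals
  pi0 <- unname(model$base_freqs)
  catr <- model$category_rates
  all_internal <- (n + 1L):n_node

  rebuild_topo <- config$topology_moves  # cached in the engine otherwise
  eval_lik <- function(dirty) {
    if (!use_lik) return(0)
    el <- ages[edge[, 1L]] - ages[edge[, 2L]]
    plik_eval(eng, edge, outer(el * rate, catr), U, Uinv, evals, pi0, dirty,
              rebuild_topo)
  }
  lik_accept <- function() if (use_lik) plik_accept(eng)
  lik_reject <- function() if (use_lik) plik_reject(eng)
  ancestors <- function(v) {  # internal nodes on the path v -> root (incl. v if internal)
    out <- integer(0)
    if (v > n) out <- v
    while (par[v] != 0L) { v <- par[v]; out <- c(out, v) }
    out
  }

  ## --- prior ---------------------------------------------------------------
  has_override <- vapply(overrides, Negate(is.null), TRUE)
  no_ov <- which(!has_override)
  ov <- which(has_override)
  # gamma log-density constants (truncation-normalised): shape, rate form
  g_km1 <- est_shape - 1
  g_inv <- 1 / est_scale
  g_const <- -est_shape * log(est_scale) - lgamma(est_shape) - est_lognorm
  lb_bp <- est_lb + ref_age
  ub_bp <- est_ub + ref_age
  tip_prior_sum <- function() {
    if (!length(est_ids)) return(0)
    y <- ages[est_idx] + ref_age
    if (any(y < lb_bp | y > ub_bp)) return(-Inf)
    s <- if (length(no_ov))
      sum(g_km1[no_ov] * log(y[no_ov]) - y[no_ov] * g_inv[no_ov] +
          g_const[no_ov]) else 0
    for (j in ov) s <- s + prior_log_density(overrides[[j]], y[j])
    s
  }
  log_prior <- function() {
    if (rate < priors$rate_min || rate > priors$rate_max) return(-Inf)
    if (pop < priors$pop_min || pop > priors$pop_max) return(-Inf)
    tp <- tip_prior_sum()
    if (!is.finite(tp)) return(-Inf)
    coalescent_log_density_ages(ages[seq_len(n)], ages[all_internal], pop) + tp
  }

  lp_cur <- log_prior()
  if (!is.finite(lp_cur)) {
    parts <- c(rate_in_bounds = rate >= priors$rate_min && rate <= priors$rate_max,
               pop_in_bounds = pop >= priors$pop_min && pop <= priors$pop_max,
               tip_priors_finite = is.finite(tip_prior_sum()))
    stop("start state has log-posterior -Inf; failing term(s): ",
         paste(names(parts)[!parts], collapse = ", "), call. = FALSE)
  }
  ll_cur <- eval_lik(all_internal)
  lik_accept()
  if (!is.finite(ll_cur))
    stop("start state has non-finite likelihood", call. = FALSE)

  ## --- move schedule -------------------------------------------------------
  internal_nonroot <- setdiff(all_internal, n + 1L)
  moves <- c("rate", "pop",
             if (length(internal_nonroot)) "node",
             "root",
             if (length(est_ids)) "tip",
             if (config$topology_moves && length(internal_nonroot)) "nx")
  w <- c(rate = 1, pop = 1, node = length(internal_nonroot), root = 1,
         tip = config$tip_move_weight * length(est_ids),
         nx = length(internal_nonroot))
  w <- w[moves]
  cumw <- cumsum(w) / sum(w)
  scales <- c(rate = 0.8, pop = 1.5, root = max(ages[n + 1L] * 0.1, 1),
              tip = max((est_ub - est_lb) / 10, 1)[1L])
  n_prop <- n_acc <- c(rate = 0, pop = 0, node = 0, root = 0, tip = 0, nx = 0)
  win_prop <- win_acc <- n_prop
  burnin_steps <- floor(config$chain_length * config$burnin_fraction)

  track_mrca <- function(lbls) {
    idxs <- match(lbls, labels)
    anc_sets <- lapply(idxs, function(v) {
      out <- integer(0)
      while (par[v] != 0L) { v <- par[v]; out <- c(out, v) }
      out
    })
    common <- Reduce(intersect, anc_sets)
    common[which.min(ages[common])]
  }

  n_samp <- (config$chain_length - burnin_steps) %/% config$sample_every
  node_names <- names(track_nodes)
  trace <- matrix(NA_real_, nrow = n_samp,
                  ncol = 6L + length(est_ids) + length(node_names))
  colnames(trace) <- c("step", "posterior", "likelihood", "prior", "rate",
                       "pop_size",
                       if (length(est_ids)) paste0("age_", est_ids),
                       if (length(node_names)) paste0("age_node_", node_names))
  samp_i <- 0L

  reflect <- function(x, lo, hi) {  # fold into [lo, hi] with period 2*span
    span <- hi - lo
    y <- (x - lo) %% (2 * span)
    if (y > span) y <- 2 * span - y
    lo + y
  }
  scale_bounds <- rbind(rate = c(0.01, 5), pop = c(0.01, 5),
                        root = c(1, 1e7),
                        tip = c(1, if (length(est_ids)) max(est_ub - est_lb) else 1))

  sample_every <- config$sample_every
  chain_length <- config$chain_length
  tunable <- names(scales)
  runif <- stats::runif; rnorm <- stats::rnorm
  for (step in seq_len(chain_length)) {
    mv <- moves[findInterval(stats::runif(1L), cumw) + 1L]
    log_hast <- 0
    dirty <- NULL
    old_rate <- rate; old_pop <- pop
    old_age <- NULL; old_node <- 0L
    nx_undo <- NULL
    ok <- TRUE

    if (mv == "rate") {
      f <- exp(scales["rate"] * (stats::runif(1L) - 0.5))
      rate <- rate * f; log_hast <- log(f)
      dirty <- all_internal
    } else if (mv == "pop") {
      f <- exp(scales["pop"] * (stats::runif(1L) - 0.5))
      pop <- pop * f; log_hast <- log(f)
    } else if (mv == "node") {
      v <- internal_nonroot[sample.int(length(internal_nonroot), 1L)]
      lo <- max(ages[chl[v, ]]); hi <- ages[par[v]]
      old_age <- ages[v]; old_node <- v
      ages[v] <- lo + stats::runif(1L) * (hi - lo)
      dirty <- ancestors(v)
    } else if (mv == "root") {
      v <- n + 1L
      lo <- max(ages[chl[v, ]])
      old_age <- ages[v]; old_node <- v
      prop <- ages[v] + stats::rnorm(1L, 0, scales["root"])
      if (prop < lo) prop <- 2 * lo - prop
      ages[v] <- prop
      dirty <- v
    } else if (mv == "tip") {
      j <- sample.int(length(est_ids), 1L)
      v <- est_idx[j]
      old_age <- ages[v]; old_node <- v
      prop <- reflect(ages[v] + stats::rnorm(1L, 0, scales["tip"]),
                      est_lb[j], est_ub[j])
      ages[v] <- prop
      if (prop >= ages[par[v]]) ok <- FALSE  # tip older than its parent
      dirty <- ancestors(v)
    } else if (mv == "nx") {
      v <- internal_nonroot[sample.int(length(internal_nonroot), 1L)]
      p <- par[v]
      sib <- chl[p, if (chl[p, 1L] == v) 2L else 1L]
      cidx <- sample.int(2L, 1L)
      cc <- chl[v, cidx]
      if (ages[v] <= ages[sib]) {
        ok <- FALSE
      } else {
        # swap: sib moves under v, cc moves under p
        e_sib <- which(edge[, 2L] == sib); e_cc <- which(edge[, 2L] == cc)
        edge[e_sib, 1L] <- v; edge[e_cc, 1L] <- p
        chl[p, which(chl[p, ] == sib)] <- cc
        chl[v, cidx] <- sib
        par[sib] <- v; par[cc] <- p
        nx_undo <- list(v = v, p = p, sib = sib, cc = cc,
                        e_sib = e_sib, e_cc = e_cc, cidx = cidx)
        dirty <- ancestors(v)
      }
    }

    n_prop[mv] <- n_prop[mv] + 1
    win_prop[mv] <- win_prop[mv] + 1
    accepted <- FALSE
    if (ok) {
      lp_prop <- log_prior()
      if (is.finite(lp_prop)) {
        if (!is.null(dirty)) {
          ll_prop <- eval_lik(dirty)
          if (log(stats::runif(1L)) <
              (ll_prop + lp_prop) - (ll_cur + lp_cur) + log_hast) {
            lik_accept(); ll_cur <- ll_prop; lp_cur <- lp_prop
            accepted <- TRUE
          } else {
            lik_reject()
          }
        } else {
          if (log(stats::runif(1L)) < lp_prop - lp_cur + log_hast) {
            lp_cur <- lp_prop
            accepted <- TRUE
          }
        }
      }
    }
    if (accepted) {
      n_acc[mv] <- n_acc[mv] + 1
      win_acc[mv] <- win_acc[mv] + 1
    } else {
      rate <- old_rate; pop <- old_pop
      if (old_node > 0L) ages[old_node] <- old_age
      if (!is.null(nx_undo)) {
        u <- nx_undo
        edge[u$e_sib, 1L] <- u$p; edge[u$e_cc, 1L] <- u$v
        chl[u$p, which(chl[u$p, ] == u$cc)] <- u$sib
        chl[u$v, u$cidx] <- u$cc
        par[u$sib] <- u$p; par[u$cc] <- u$v
      }
    }

    # auto-tune proposal scales during burn-in only
    if (step <= burnin_steps && mv %in% tunable &&
        win_prop[mv] >= 50) {
      a <- win_acc[mv] / win_prop[mv]
      scales[mv] <- min(max(scales[mv] * exp(a - 0.3), scale_bounds[mv, 1L]),
                        scale_bounds[mv, 2L])
      win_prop[mv] <- win_acc[mv] <- 0
    }

    if (step > burnin_steps && step %% sample_every == 0L) {
      samp_i <- samp_i + 1L
      node_ages <- if (length(node_names))
        vapply(track_nodes, function(ls) ages[track_mrca(ls)], 0) + ref_age
      trace[samp_i, ] <- c(step, ll_cur + lp_cur, ll_cur, lp_cur, rate, pop,
                           if (length(est_ids)) ages[est_idx] + ref_age,
                           if (length(node_names)) node_ages)
    }
  }

  out <- as.data.frame(trace[seq_len(samp_i), , drop = FALSE])
  attr(out, "acceptance") <- ifelse(n_prop > 0, n_acc / n_prop, NA)
  attr(out, "scales") <- scales
  attr(out, "seed") <- config$seed
  attr(out, "replicate") <- replicate
  class(out) <- c("mcmc_trace", "data.frame")
  out
}
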