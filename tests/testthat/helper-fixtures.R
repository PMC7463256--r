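# Shared fixtures and independent oracles.

# fixed 4-taxon serial-sample tree used across likelihood tests
fixture_tree4 <- function() {
  timetree(rbind(c(5L, 6L), c(5L, 4L), c(6L, 7L), c(6L, 3L),
                 c(7L, 1L), c(7L, 2L)),
           c("t1", "t2", "t3", "t4"),
           c(0, 10, 25, 5, 100, 60, 30))
}

fixture_model <- function(rate = 0.004, kappa = 5, alpha = 0.6,
                          freqs = c(0.35, 0.18, 0.22, 0.25)) {
  subst_model(kappa, freqs, alpha, rate)
}

# brute-force likelihood by enumerating internal-node states, with
# transition matrices from a numerical matrix exponential (independent of
# the closed-form spectral path used by the package)
brute_force_loglik <- function(tree, aln, model) {
  codes <- tipdater:::aln_codes(aln)[tree$tip_labels, , drop = FALSE]
  n <- tree$n_tip
  freqs <- unname(model$base_freqs)
  Q <- tipdater:::hky_q_matrix(model$kappa, freqs)
  cr <- model$category_rates
  n_int <- n - 1L
  state_grid <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  total <- 0
  Ps <- lapply(seq_len(model$n_categories), function(cat)
    lapply(seq_len(nrow(tree$edge)), function(e) {
      el <- tree$ages[tree$edge[e, 1L]] - tree$ages[tree$edge[e, 2L]]
      as.matrix(Matrix::expm(Q * model$rate * cr[cat] * el))
    }))
  for (s in seq_len(ncol(codes))) {
    sitelik <- 0
    for (cat in seq_len(model$n_categories)) {
      P <- Ps[[cat]]
      tot <- 0
      for (r in seq_len(nrow(state_grid))) {
        st <- c(codes[, s] + 1L, state_grid[r, ])
        p <- freqs[st[n + 1L]]
        for (e in seq_len(nrow(tree$edge))) {
          child <- tree$edge[e, 2L]
          if (child <= n && codes[child, s] == 4L) next  # missing tip
          p <- p * P[[e]][st[tree$edge[e, 1L]], st[child]]
        }
        tot <- tot + p
      }
      sitelik <- sitelik + tot / model$n_categories
    }
    total <- total + log(sitelik)
  }
  total
}

# CDF of the study's tip-age prior: Exp(mean 200 ky) truncated to
# [50 ky, 800 ky] BP
truncated_exp_cdf <- function(q, mean = 2e5, lo = 5e4, hi = 8e5) {
  (stats::pexp(q / mean) - stats::pexp(lo / mean)) /
    (stats::pexp(hi / mean) - stats::pexp(lo / mean))
}

# push internal ages up so every parent is strictly older than its children
repair_tree_ages <- function(tree) {
  n <- tree$n_tip
  ch <- tipdater:::children_matrix(tree)
  ages <- tree$ages
  fix <- function(v) {
    if (v <= n) return(ages[v])
    lo <- max(vapply(ch[v - n, ], fix, 0))
    if (ages[v] <= lo) ages[v] <<- lo * 1.01 + 1
    ages[v]
  }
  fix(n + 1L)
  ages
}

# small serial alignment + matching date table for sampler tests
fixture_dating_problem <- function(n_tips = 10, seq_length = 4000,
                                   n_undated = 2, rate = 3e-8,
                                   pop_size = 1e5, age_span = 2.5e5,
                                   alpha = 0.3, kappa = 20, seed = 1,
                                   ref_age = 13000) {
  set.seed(seed)
  tip_rel <- c(0, sort(stats::runif(n_tips - 1, 0, age_span)))
  tree <- simulate_coalescent_tree(tip_rel, pop_size, seed = seed + 1)
  aln <- simulate_sequences(tree, rate, kappa, alpha,
                            c(0.32, 0.26, 0.13, 0.29), seq_length,
                            seed = seed + 2)
  undated <- order(tip_rel, decreasing = TRUE)[seq_len(n_undated)]
  tab <- data.frame(
    id = tree$tip_labels,
    status = ifelse(seq_along(tip_rel) %in% undated, "estimated", "fixed"),
    age_bp = ifelse(seq_along(tip_rel) %in% undated, NA, tip_rel + ref_age),
    lower_bp = ref_age, upper_bp = 800000
  )
  list(tree = tree, alignment = aln, spec = tip_date_spec(tab),
       truth = list(tip_rel = tip_rel, rate = rate, pop_size = pop_size,
                    undated = undated, ref_age = ref_age),
       model = subst_model(kappa, empirical_base_freqs(aln), alpha, rate))
}
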