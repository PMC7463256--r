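#' Default HKY+G4 model for a dating analysis
#'
#' Builds a [subst_model] with empirical base frequencies counted from the
#' alignment, as the dating analyses use.
#'
#' @param alignment a [dna_alignment].
#' @param kappa transition/transversion ratio (default 20, a typical
#'   mitochondrial value).
#' @param alpha gamma shape (default 0.1, strong among-site rate variation as
#'   is typical for mitogenomes).
#' @param rate initial clock rate (overridden by the sampler's rate
#'   parameter).
#' @return a [subst_model].
#' @export
default_model <- function(alignment, kappa = 20, alpha = 0.1, rate = 1e-8) {
  subst_model(kappa, empirical_base_freqs(alignment), alpha, rate)
}

## shared machinery: run replicate chains, pool post-burn-in samples
run_replicates <- function(alignment, start_tree, tip_spec, priors, model,
                           config, tip_prior_overrides = NULL,
                           track_nodes = NULL) {
  traces <- lapply(seq_len(config$n_replicates), function(r) {
    tr <- mcmc_run(alignment, start_tree, tip_spec, priors, model, config,
                   tip_prior_overrides = tip_prior_overrides,
                   track_nodes = track_nodes, replicate = r)
    tr$chain <- r
    tr
  })
  pooled <- do.call(rbind, traces)
  class(pooled) <- c("mcmc_trace", "data.frame")
  list(pooled = pooled, traces = traces)
}

#' Joint dating of all undated tips
#'
#' Runs a single analysis in which the ages of every estimated tip are free
#' parameters of one chain (the paper-style "Joint" procedure), in replicate,
#' and summarises the pooled post-burn-in samples.
#'
#' @inheritParams mcmc_run
#' @param clade_mrca optional named list of tip-label vectors whose MRCA ages
#'   are tracked and summarised.
#' @return a list of class `dating_result`: `summaries` (per estimated tip
#'   and tracked node: median, 95% HPD, ESS, mode — ages in years BP),
#'   `trace` (pooled), `traces` (per replicate), `per_chain_medians`.
#' @export
joint_dating <- function(alignment, start_tree, tip_spec, priors, model,
                         config, clade_mrca = NULL) {
  if (length(estimated_ids(tip_spec)) == 0L && is.null(clade_mrca))
    stop("nothing to estimate: no undated tips and no tracked nodes",
         call. = FALSE)
  rr <- run_replicates(alignment, start_tree, tip_spec, priors, model,
                       config, track_nodes = clade_mrca)
  est <- intersect(estimated_ids(tip_spec), start_tree$tip_labels)
  targets <- c("rate", "pop_size",
               if (length(est)) paste0("age_", est),
               if (!is.null(clade_mrca)) paste0("age_node_", names(clade_mrca)))
  summaries <- summarize_trace(rr$pooled, targets = targets)
  per_chain <- vapply(rr$traces, function(tr)
    vapply(targets, function(p) stats::median(tr[[p]]), 0),
    numeric(length(targets)))
  structure(list(procedure = "joint", summaries = summaries,
                 trace = rr$pooled, traces = rr$traces,
                 per_chain_medians = per_chain),
            class = "dating_result")
}

#' @export
print.dating_result <- function(x, ...) {
  cat("Tip-dating result (", x$procedure, " procedure)\n", sep = "")
  print(x$summaries, digits = 4)
  invisible(x)
}

#' Two-stage individually-dated procedure
#'
#' Stage 1 estimates the age of each undated tip in its own analysis that
#' contains only the fixed-date tips plus that one tip. Stage 2 refits each
#' stage-1 marginal posterior as a reusable prior density ([fit_prior],
#' boundary-reflected KDE). Stage 3 runs a combined analysis of all tips in
#' which those refitted densities replace the original gamma priors. This is
#' the paper-style "Individually Dated" procedure: it suppresses the mutual
#' interaction of many simultaneously free tip ages.
#'
#' @inheritParams joint_dating
#' @param stage1_config optional [mcmc_config] for the per-tip stage-1 runs
#'   (defaults to `config`).
#' @return a `dating_result` as for [joint_dating], with stage-1 summaries in
#'   `$stage1` and the refitted priors in `$stage2_priors`.
#' @export
individual_dating <- function(alignment, start_tree, tip_spec, priors, model,
                              config, clade_mrca = NULL,
                              stage1_config = NULL) {
  est <- intersect(estimated_ids(tip_spec), start_tree$tip_labels)
  if (length(est) == 0L) stop("no undated tips to estimate", call. = FALSE)
  if (is.null(stage1_config)) stage1_config <- config
  fixed_ids <- intersect(tip_spec$table$id[tip_spec$table$status == "fixed"],
                         start_tree$tip_labels)

  stage1 <- lapply(est, function(id) {
    keep <- c(fixed_ids, id)
    sub_tree <- keep_tips(start_tree, keep)
    sub_spec <- tip_date_spec(tip_spec$table[tip_spec$table$id %in% keep, ],
                              bounds_scale = "absolute")
    sub_aln <- dna_alignment(alignment$seqs[keep], keep)
    rr <- run_replicates(sub_aln, sub_tree, sub_spec, priors, model,
                         stage1_config)
    list(id = id, samples = rr$pooled[[paste0("age_", id)]],
         summary = summarize_trace(rr$pooled, targets = paste0("age_", id)))
  })
  names(stage1) <- est

  stage2 <- lapply(stage1, function(s1) {
    row <- tip_spec$table[tip_spec$table$id == s1$id, ]
    fit_prior(s1$samples, row$lower_bp, row$upper_bp)
  })
  names(stage2) <- est

  rr <- run_replicates(alignment, start_tree, tip_spec, priors, model,
                       config, tip_prior_overrides = stage2,
                       track_nodes = clade_mrca)
  targets <- c("rate", "pop_size", paste0("age_", est),
               if (!is.null(clade_mrca)) paste0("age_node_", names(clade_mrca)))
  summaries <- summarize_trace(rr$pooled, targets = targets)
  structure(list(procedure = "individual", summaries = summaries,
                 trace = rr$pooled, traces = rr$traces,
                 stage1 = lapply(stage1, `[[`, "summary"),
                 stage2_priors = stage2),
            class = "dating_result")
}
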