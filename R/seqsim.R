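#' Simulate sequences along a time-tree under HKY+G4
#'
#' Draws a root sequence from the stationary base frequencies, assigns each
#' site to one of the discrete-gamma rate categories uniformly at random, and
#' evolves the sequence down every branch using the HKY transition-probability
#' matrix for that branch's duration and the site's category rate. Optionally
#' masks a fraction of each sequence with runs of `N`, emulating the patchy
#' coverage of ancient-DNA consensus sequences.
#'
#' @param tree a [timetree] with ages in years.
#' @param rate clock rate in substitutions/site/year.
#' @param kappa transition/transversion rate ratio.
#' @param alpha gamma shape for among-site rate variation.
#' @param base_freqs length-4 simplex over A, C, G, T.
#' @param seq_length number of sites.
#' @param seed integer seed (mandatory).
#' @param missing_frac fraction of sites per sequence masked to `N` in
#'   contiguous runs (default 0).
#' @param missing_run_mean mean length of an `N` run, in sites (default 300).
#' @return a [dna_alignment] with one row per tip, plus attribute
#'   `"site_categories"` (the gamma category of each site).
#' @export
simulate_sequences <- function(tree, rate, kappa, alpha, base_freqs,
                               seq_length, seed, missing_frac = 0,
                               missing_run_mean = 300) {
  if (!inherits(tree, "timetree")) stop("tree must be a timetree", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  base_freqs <- as.numeric(base_freqs)
  if (length(base_freqs) != 4L || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-12)
    stop("base_freqs must be a length-4 simplex summing to 1", call. = FALSE)
  if (missing_frac < 0 || missing_frac >= 1)
    stop("missing_frac must be in [0, 1)", call. = FALSE)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  L <- as.integer(seq_length)
  # rate 0 is a valid degenerate case: every tip inherits the root draw
  model <- if (rate > 0) subst_model(kappa, base_freqs, alpha, rate) else
    subst_model(kappa, base_freqs, alpha, 1)
  ncat <- model$n_categories
  n <- tree$n_tip
  n_node <- 2L * n - 1L

  site_cat <- sample.int(ncat, L, replace = TRUE)
  states <- matrix(0L, nrow = n_node, ncol = L)  # 1..4
  root <- n + 1L
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = base_freqs)

  # preorder: parents before children; order edges by parent age descending
  ord <- order(tree$ages[tree$edge[, 1L]], decreasing = TRUE)
  for (e in ord) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    if (rate == 0) { states[ch, ] <- states[p, ]; next }
    el <- tree$ages[p] - tree$ages[ch]
    for (cat in seq_len(ncat)) {
      P <- hky_transition_matrix(model, el, model$category_rates[cat])
      in_cat <- site_cat == cat
      for (s in 1:4) {
        idx <- which(in_cat & states[p, ] == s)
        if (length(idx))
          states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }

  tip_codes <- states[seq_len(n), , drop = FALSE] - 1L  # 0..3
  if (missing_frac > 0) {
    for (i in seq_len(n))
      tip_codes[i, mask_runs(L, missing_frac, missing_run_mean)] <- 4L
  }
  rownames(tip_codes) <- tree$tip_labels
  aln <- codes_to_alignment(tip_codes)
  attr(aln, "site_categories") <- site_cat
  aln
}

## sample contiguous runs of sites until ~frac of the sequence is covered
mask_runs <- function(L, frac, run_mean) {
  target <- frac * L
  masked <- logical(L)
  while (sum(masked) < target) {
    len <- min(L, 1L + stats::rgeom(1L, 1 / run_mean))
    start <- sample.int(max(1L, L - len + 1L), 1L)
    masked[start:(start + len - 1L)] <- TRUE
  }
  which(masked)
}
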