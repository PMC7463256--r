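#' Phylogenetic log-likelihood under HKY+G4 by Felsenstein pruning
#'
#' Computes the log-probability of an alignment given a time-tree and a
#' [subst_model], by pruning over compressed site patterns and averaging the
#' four discrete-gamma categories with equal weight. `N` and `-` are treated
#' as fully missing data (a conditional-likelihood vector of ones), so an
#' all-missing alignment has log-likelihood 0 regardless of the tree.
#'
#' @param tree a [timetree]; its tip labels must all appear in `alignment`.
#' @param alignment a [dna_alignment].
#' @param model a [subst_model]; branch expected substitutions are
#'   `model$rate * category_rate * (age[parent] - age[child])`.
#' @return the log-likelihood (natural log).
#' @export
log_likelihood <- function(tree, alignment, model) {
  if (!inherits(tree, "timetree")) stop("tree must be a timetree", call. = FALSE)
  if (!inherits(alignment, "dna_alignment"))
    stop("alignment must be a dna_alignment", call. = FALSE)
  if (!all(tree$tip_labels %in% alignment$ids))
    stop("alignment is missing tree tip(s): ",
         paste(setdiff(tree$tip_labels, alignment$ids), collapse = ", "),
         call. = FALSE)
  codes <- aln_codes(alignment)[tree$tip_labels, , drop = FALSE]
  pat <- compress_patterns(codes)
  eng <- plik_init(pat$patterns, pat$weights, model$n_categories)
  el <- tree$ages[tree$edge[, 1L]] - tree$ages[tree$edge[, 2L]]
  subs <- outer(el * model$rate, model$category_rates)
  ll <- plik_eval(eng, tree$edge, subs, model$U, model$Uinv, model$evals,
                  unname(model$base_freqs),
                  (tree$n_tip + 1L):(2L * tree$n_tip - 1L))
  plik_accept(eng)
  ll
}
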