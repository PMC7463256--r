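#' Nucleotide diversity of a clade
#'
#' Nucleotide diversity (pi) of a group of sequences, computed as the mean of
#' all pairwise F84 distances between its members, with the sample standard
#' deviation of those distances. Undefined (saturated or siteless) pairs are
#' excluded with a warning and reflected in `n_pairs`.
#'
#' @param alignment a [dna_alignment].
#' @param members character vector of two or more sequence ids.
#' @param freqs frequency convention passed to [distance_matrix].
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a list with `pi`, `sd`, `n_pairs` (pairs actually used), and
#'   `n_members`. For exactly two members `sd` is `NA` and the single value
#'   is also reported as `distance`, mirroring how a two-specimen clade is a
#'   distance, not a diversity.
#' @export
nucleotide_diversity <- function(alignment, members,
                                 freqs = c("pair", "global"),
                                 sd_type = c("sample", "population")) {
  freqs <- match.arg(freqs)
  sd_type <- match.arg(sd_type)
  if (length(members) < 2L)
    stop("need at least 2 members to compute diversity", call. = FALSE)
  missing_ids <- setdiff(members, alignment$ids)
  if (length(missing_ids))
    stop("unknown sequence id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  sub <- dna_alignment(alignment$seqs[members], members)
  D <- distance_matrix(sub, freqs = freqs)
  d <- D[upper.tri(D)]
  n_total <- length(d)
  d <- d[!is.na(d)]
  if (length(d) == 0L)
    stop("all pairwise distances are undefined", call. = FALSE)
  if (length(d) < n_total)
    warning(n_total - length(d), " undefined pairwise distance(s) excluded",
            call. = FALSE)
  s <- if (length(d) < 2L) NA_real_
       else if (sd_type == "sample") stats::sd(d)
       else stats::sd(d) * sqrt((length(d) - 1) / length(d))
  out <- list(pi = mean(d), sd = s, n_pairs = length(d),
              n_members = length(members))
  if (length(members) == 2L) out$distance <- mean(d)
  out
}

#' Long-format pairwise distance and diversity table for clades
#'
#' Emits every pairwise F84 distance between members of the named clades
#' (both clade labels attached), plus one summary row per analysis variant
#' giving the [nucleotide_diversity] of the member set the variant selects.
#' Variants express the inclusion toggles of the heatmap analysis, e.g. a
#' clade with and without a temporally distinct member.
#'
#' @param alignment a [dna_alignment].
#' @param clade_assignment data frame with columns `tip` and `clade`; every
#'   tip must be present in the alignment.
#' @param variants named list; each element is a list with `clade` (label)
#'   and optionally `exclude` (tips to drop) or `members` (explicit member
#'   set). Defaults to one variant per clade with >= 2 members.
#' @param freqs frequency convention passed to [distance_matrix].
#' @return a list with `pairs` (long data frame: `tip_a`, `tip_b`, `clade_a`,
#'   `clade_b`, `distance`) and `summaries` (one row per variant: `variant`,
#'   `clade`, `n_members`, `n_pairs`, `pi`, `sd`).
#' @export
clade_distance_table <- function(alignment, clade_assignment, variants = NULL,
                                 freqs = c("pair", "global")) {
  freqs <- match.arg(freqs)
  stopifnot(is.data.frame(clade_assignment),
            all(c("tip", "clade") %in% names(clade_assignment)))
  tips <- as.character(clade_assignment$tip)
  missing_ids <- setdiff(tips, alignment$ids)
  if (length(missing_ids))
    stop("clade table names tip(s) absent from the alignment: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  clade_of <- stats::setNames(as.character(clade_assignment$clade), tips)

  sub <- dna_alignment(alignment$seqs[tips], tips)
  D <- distance_matrix(sub, freqs = freqs)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  pairs <- data.frame(
    tip_a = tips[idx[, 1L]], tip_b = tips[idx[, 2L]],
    clade_a = clade_of[tips[idx[, 1L]]], clade_b = clade_of[tips[idx[, 2L]]],
    distance = D[idx], row.names = NULL, stringsAsFactors = FALSE
  )

  if (is.null(variants)) {
    cl <- split(tips, clade_of[tips])
    cl <- cl[vapply(cl, length, 1L) >= 2L]
    variants <- lapply(names(cl), function(x) list(clade = x))
    names(variants) <- names(cl)
  }
  summaries <- do.call(rbind, lapply(names(variants), function(vn) {
    v <- variants[[vn]]
    members <- if (!is.null(v$members)) as.character(v$members)
               else tips[clade_of[tips] == v$clade]
    if (!is.null(v$exclude)) {
      unknown <- setdiff(v$exclude, tips)
      if (length(unknown))
        stop("variant '", vn, "' excludes unknown tip(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      members <- setdiff(members, v$exclude)
    }
    nd <- nucleotide_diversity(alignment, members, freqs = freqs)
    data.frame(variant = vn, clade = if (!is.null(v$clade)) v$clade else NA,
               n_members = nd$n_members, n_pairs = nd$n_pairs,
               pi = nd$pi, sd = nd$sd, stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, summaries = summaries)
}
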