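#' Filter mapped fragments by length and mapping quality
#'
#' Retains fragments with length >= `min_length` and mapping quality >=
#' `min_mapq` (both boundaries inclusive), preserving input order. Defaults
#' are the ancient-DNA curation thresholds of 24 bp and MAPQ 30.
#'
#' @param reads a [read_set].
#' @param min_length minimum fragment length in bp (default 24).
#' @param min_mapq minimum mapping quality (default 30).
#' @return the filtered [read_set].
#' @export
filter_reads <- function(reads, min_length = 24, min_mapq = 30) {
  if (min_length < 0 || min_mapq < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  keep <- (reads$end - reads$start) >= min_length & reads$mapq >= min_mapq
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove duplicate fragments by unique 5' and 3' positions
#'
#' Keeps one fragment per unique `(start, end, strand)` triple — i.e. per
#' unique pair of 5' and 3' mapping coordinates. Ties are broken by highest
#' mapping quality, then by first encounter; the retained fragments keep
#' their original relative order.
#'
#' @param reads a [read_set].
#' @return the deduplicated [read_set].
#' @export
deduplicate <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  key <- paste(reads$start, reads$end, reads$strand, sep = "|")
  ord <- order(-reads$mapq, seq_len(nrow(reads)))  # best mapq, then first seen
  winner <- ord[!duplicated(key[ord])]
  out <- reads[sort(winner), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag abnormally deep, multiallelic positions
#'
#' Returns the 0-based positions whose depth exceeds the across-position mean
#' by more than `sd_multiplier` standard deviations AND that carry at least
#' two distinct bases each supported by at least `min_minor_count` reads.
#' Such positions arise from reads stacking on conserved regions and are
#' masked rather than called. The depth mean and SD are computed over covered
#' positions only by default (`covered_only = TRUE`), so uncovered flanks do
#' not deflate them.
#'
#' @param site_counts a `site_counts` data frame (see [make_pileup]).
#' @param sd_multiplier depth threshold in standard deviations (default 3).
#' @param min_minor_count minimum reads supporting each allele for a position
#'   to count as multiallelic (default 2).
#' @param covered_only whether the depth mean/SD use only positions with
#'   depth >= 1.
#' @return integer vector of 0-based positions (possibly empty).
#' @export
mask_high_coverage_multiallelic <- function(site_counts, sd_multiplier = 3,
                                            min_minor_count = 2,
                                            covered_only = TRUE) {
  depth <- site_counts$depth
  base_counts <- as.matrix(site_counts[, BASES])
  if (any(base_counts < 0)) stop("negative base counts", call. = FALSE)
  use <- if (covered_only) depth >= 1L else rep(TRUE, length(depth))
  if (!any(use)) return(integer(0))
  mu <- mean(depth[use]); sdv <- stats::sd(depth[use])
  if (is.na(sdv)) sdv <- 0
  deep <- depth > mu + sd_multiplier * sdv
  multi <- rowSums(base_counts >= min_minor_count) >= 2L
  site_counts$position[deep & multi]
}

#' Majority-call a consensus sequence with curation masking
#'
#' Calls the strictly most frequent base at each position and masks with `N`:
#' positions below `min_depth` (`low_depth`), positions inside the supplied
#' region mask such as the VNTR (`region_mask`), abnormally deep multiallelic
#' positions per [mask_high_coverage_multiallelic] (`high_cov_multiallelic`),
#' and tied majority calls (`tie`). Completeness is the fraction of non-`N`
#' positions over the whole reference, and a sequence is classified complete
#' when completeness exceeds 0.80.
#'
#' @param site_counts a `site_counts` data frame covering every reference
#'   position contiguously.
#' @param min_depth minimum depth to call a base (default 3).
#' @param region_mask optional data frame with 0-based half-open `start`,
#'   `end` columns (BED-style intervals) to force to `N`.
#' @param high_cov if `TRUE` (default) also apply
#'   [mask_high_coverage_multiallelic] with `sd_multiplier`/`min_minor_count`.
#' @param sd_multiplier,min_minor_count passed through to the high-coverage
#'   rule.
#' @return a list of class `consensus_result`: `sequence` (string),
#'   `mask_reasons` (factor per position: `none`, `low_depth`,
#'   `high_cov_multiallelic`, `region_mask`, `tie`), `completeness`,
#'   `is_complete`.
#' @export
call_consensus <- function(site_counts, min_depth = 3, region_mask = NULL,
                           high_cov = TRUE, sd_multiplier = 3,
                           min_minor_count = 2) {
  base_counts <- as.matrix(site_counts[, BASES])
  if (any(base_counts < 0)) stop("negative base counts", call. = FALSE)
  L <- nrow(site_counts)
  if (!identical(as.integer(site_counts$position), 0:(L - 1L)))
    stop("site counts must cover positions 0..L-1 contiguously", call. = FALSE)
  depth <- site_counts$depth

  top <- max.col(base_counts, ties.method = "first")
  top_count <- base_counts[cbind(seq_len(L), top)]
  tied <- rowSums(base_counts == top_count) > 1L

  reason <- rep("none", L)
  call <- BASES[top]
  reason[tied] <- "tie"
  if (high_cov) {
    hc <- mask_high_coverage_multiallelic(site_counts, sd_multiplier,
                                          min_minor_count)
    reason[site_counts$position %in% hc] <- "high_cov_multiallelic"
  }
  reason[depth < min_depth] <- "low_depth"
  if (!is.null(region_mask) && nrow(region_mask)) {
    for (i in seq_len(nrow(region_mask))) {
      lo <- region_mask$start[i]; hi <- region_mask$end[i]
      reason[site_counts$position >= lo & site_counts$position < hi] <- "region_mask"
    }
  }
  call[reason != "none"] <- "N"
  completeness <- mean(call != "N")
  structure(
    list(sequence = paste(call, collapse = ""),
         mask_reasons = factor(reason, levels = c("none", "low_depth",
                                                  "high_cov_multiallelic",
                                                  "region_mask", "tie")),
         completeness = completeness,
         is_complete = completeness > 0.80),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus of", nchar(x$sequence), "positions;",
      sprintf("completeness %.1f%%", 100 * x$completeness),
      if (x$is_complete) "(complete)\n" else "(incomplete)\n")
  print(table(x$mask_reasons))
  invisible(x)
}

#' Terminal deamination damage profile
#'
#' For each offset from the fragment 5' end (in read orientation), the
#' frequency of reference-`C` positions read as `T`; symmetrically, for each
#' offset from the 3' end, the frequency of reference-`G` read as `A`.
#' Offsets with no qualifying reference base covered are reported as `NA`
#' (missing), never as zero. Minus-strand fragments are reverse-complemented
#' (together with their reference window) before offsets are measured, so
#' damage is always measured from the molecule's own ends.
#'
#' @param reads a [read_set].
#' @param reference the reference sequence string.
#' @param window number of terminal positions profiled from each end
#'   (default 15).
#' @return data frame with columns `offset` (0-based), `c_to_t_5p`,
#'   `n_c_5p`, `g_to_a_3p`, `n_g_3p`.
#' @export
damage_profile <- function(reads, reference, window = 15) {
  reference <- toupper(reference)
  n <- nrow(reads)
  frag <- reads$seq
  refw <- substring(reference, reads$start + 1L, reads$end)
  minus <- reads$strand == "-"
  if (any(minus)) {
    frag[minus] <- revcomp(frag[minus])
    refw[minus] <- revcomp(refw[minus])
  }
  lens <- nchar(frag)
  ct <- nc <- ga <- ng <- integer(window)
  for (off in seq_len(window) - 1L) {
    ok <- lens > off
    # 5' side
    rb <- substr(refw[ok], off + 1L, off + 1L)
    ob <- substr(frag[ok], off + 1L, off + 1L)
    isc <- rb == "C"
    nc[off + 1L] <- sum(isc)
    ct[off + 1L] <- sum(isc & ob == "T")
    # 3' side
    p3 <- lens[ok] - off
    rb <- substr(refw[ok], p3, p3)
    ob <- substr(frag[ok], p3, p3)
    isg <- rb == "G"
    ng[off + 1L] <- sum(isg)
    ga[off + 1L] <- sum(isg & ob == "A")
  }
  data.frame(offset = seq_len(window) - 1L,
             c_to_t_5p = ifelse(nc > 0L, ct / nc, NA_real_), n_c_5p = nc,
             g_to_a_3p = ifelse(ng > 0L, ga / ng, NA_real_), n_g_3p = ng)
}
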