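#' Read and write FASTA alignments
#'
#' `read_fasta` folds mixed case to uppercase, rejects `U`, and errors on
#' ragged alignments naming the offending records. IUPAC ambiguity codes
#' other than `N` are folded to `N` with a warning. `write_fasta` writes
#' 70-column wrapped records; a write-read round trip is the identity.
#'
#' @param path file path.
#' @return `read_fasta`: a [dna_alignment].
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    toupper(paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""))
  }, "")
  seqs <- gsub("\\s", "", seqs)
  if (any(grepl("U", seqs, fixed = TRUE)))
    stop("RNA alphabet (U) is not supported", call. = FALSE)
  amb <- grepl("[^ACGTN-]", seqs)
  if (any(amb)) {
    warning("IUPAC ambiguity codes folded to N in: ",
            paste(ids[amb], collapse = ", "), call. = FALSE)
    seqs <- gsub("[^ACGTN-]", "N", seqs)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment; offending record(s): ",
         paste(ids[lens != stats::median(lens)], collapse = ", "),
         call. = FALSE)
  dna_alignment(seqs, ids)
}

#' @rdname read_fasta
#' @param alignment a [dna_alignment].
#' @export
write_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment$ids)) {
    writeLines(paste0(">", alignment$ids[i]), con)
    s <- alignment$seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write time-trees
#'
#' Newick/NEXUS trees with branch lengths in years. On reading, node ages
#' are recomputed from root-to-tip path lengths (deepest tip at age 0); a
#' tip-date table can pin and cross-check the ages. Polytomies are an error:
#' the samplers require strictly binary trees.
#'
#' @param path file path.
#' @param format `"newick"` or `"nexus"`.
#' @param tip_ages optional named vector of tip ages in years before the
#'   youngest tip, checked against the branch lengths (see
#'   [timetree_from_phylo]).
#' @return `read_tree`: a [timetree].
#' @export
read_tree <- function(path, format = c("newick", "nexus"), tip_ages = NULL) {
  format <- match.arg(format)
  phy <- if (format == "newick") ape::read.tree(path) else ape::read.nexus(path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  timetree_from_phylo(phy, tip_ages = tip_ages)
}

#' @rdname read_tree
#' @param tree a [timetree].
#' @export
write_tree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  phy <- as_phylo(tree)
  if (format == "newick") ape::write.tree(phy, file = path)
  else ape::write.nexus(phy, file = path)
  invisible(path)
}

#' Read a tip-date table
#'
#' Tab-separated table with columns `id`, `status` (`fixed`/`estimated`),
#' `age_bp`, and optional `lower_bp`, `upper_bp`, `prior_shape`,
#' `prior_scale`.
#'
#' @param path file path.
#' @param bounds_scale passed to [tip_date_spec].
#' @return a [tip_date_spec].
#' @export
read_tipdates <- function(path, bounds_scale = "absolute") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tip_date_spec(df, bounds_scale = bounds_scale)
}

#' Read and write site-count (pileup) tables
#'
#' Tab-separated with columns `position` (0-based), `A`, `C`, `G`, `T`,
#' `depth`.
#'
#' @param path file path.
#' @return `read_site_counts`: a `site_counts` data frame.
#' @export
read_site_counts <- function(path) {
  sc <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(sc)))
    stop("site-count table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(sc$depth)) sc$depth <- rowSums(sc[, BASES])
  if (any(abs(sc$depth - rowSums(sc[, BASES])) > 0))
    stop("depth column disagrees with base counts", call. = FALSE)
  class(sc) <- c("site_counts", "data.frame")
  sc
}

#' @rdname read_site_counts
#' @param site_counts a `site_counts` data frame.
#' @export
write_site_counts <- function(site_counts, path) {
  utils::write.table(site_counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write BED interval masks
#'
#' Standard 0-based half-open BED intervals (first three columns used).
#'
#' @param path file path.
#' @return `read_bed`: data frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(df[, 1:3], c("chrom", "start", "end"))
}

#' @rdname read_bed
#' @param intervals data frame with `chrom` (optional), `start`, `end`.
#' @export
write_bed <- function(intervals, path) {
  if (is.null(intervals$chrom)) intervals$chrom <- "ref"
  utils::write.table(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an MCMC trace as a tab-separated log
#'
#' BEAST-style columns: `state`, `posterior`, `likelihood`, `prior`,
#' `clock.rate`, `pop.size`, then one column per estimated tip age and
#' tracked node.
#'
#' @param trace an `mcmc_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  names(df)[match(c("step", "rate", "pop_size"), names(df))] <-
    c("state", "clock.rate", "pop.size")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
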