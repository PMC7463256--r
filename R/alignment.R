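#' Multiple-sequence alignments
#'
#' A `dna_alignment` holds equal-length aligned sequences over the alphabet
#' `A C G T N -` (uppercase), with unique ids. `N` and `-` are both treated as
#' fully missing data by every downstream computation.
#'
#' @param seqs character vector of aligned sequences (one string per record).
#' @param ids character vector of unique sequence ids.
#' @return an object of class `dna_alignment`.
#' @export
dna_alignment <- function(seqs, ids = names(seqs)) {
  if (is.null(ids)) stop("sequence ids are required", call. = FALSE)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(seqs) != length(ids)) stop("ids and seqs lengths differ", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  len <- unique(nchar(seqs))
  if (length(len) > 1L) {
    bad <- ids[nchar(seqs) != nchar(seqs)[1L]]
    stop("alignment is ragged; offending record(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(grepl("U", seqs, fixed = TRUE)))
    stop("RNA alphabet (U) is not supported", call. = FALSE)
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("sequences contain characters outside {A,C,G,T,N,-}: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  structure(list(ids = ids, seqs = stats::setNames(seqs, ids),
                 n_sites = if (length(len)) len else 0L),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("dna_alignment:", length(x$ids), "sequences x", x$n_sites, "sites\n")
  invisible(x)
}

## integer codes: A=0 C=1 G=2 T=3, N/- = 4 (missing); matrix n_seq x n_sites
aln_codes <- function(aln) {
  chars <- strsplit(aln$seqs, "", fixed = TRUE)
  m <- matrix(0L, nrow = length(aln$ids), ncol = aln$n_sites)
  lut <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L, `-` = 4L)
  for (i in seq_along(chars)) m[i, ] <- lut[chars[[i]]]
  rownames(m) <- aln$ids
  m
}

codes_to_alignment <- function(m, ids = rownames(m)) {
  lut <- c("A", "C", "G", "T", "N")
  seqs <- apply(m, 1L, function(r) paste(lut[r + 1L], collapse = ""))
  dna_alignment(seqs, ids)
}

## compress alignment columns into unique site patterns with weights
compress_patterns <- function(codes) {
  if (ncol(codes) == 0L)
    return(list(patterns = codes, weights = numeric(0)))
  keys <- do.call(paste, c(asplit(codes, 1L), sep = ","))
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  list(patterns = codes[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(first))))
}

#' Empirical base frequencies of an alignment
#'
#' Counts A, C, G, T over the whole alignment, excluding `N` and gaps, and
#' normalises to a simplex.
#'
#' @param aln a [dna_alignment].
#' @return named numeric vector of length 4.
#' @export
empirical_base_freqs <- function(aln) {
  codes <- aln_codes(aln)
  counts <- tabulate(codes + 1L, nbins = 5L)[1:4]
  if (sum(counts) == 0) stop("alignment has no called bases", call. = FALSE)
  stats::setNames(counts / sum(counts), BASES)
}
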