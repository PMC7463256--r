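#' Degraded ancient-DNA read sets
#'
#' A `read_set` is a data frame of mapped sequencing fragments with columns
#' `start`, `end` (0-based half-open reference coordinates), `strand`
#' (`"+"`/`"-"`), `seq` (the fragment sequence in reference orientation) and
#' `mapq` (mapping quality). It emulates the deduplicated, filtered read
#' records that consensus curation starts from.
#'
#' @param start,end integer vectors, 0-based half-open, `start < end`.
#' @param strand character vector of `"+"`/`"-"`.
#' @param seq character vector of fragment sequences over `A C G T N`.
#' @param mapq numeric vector of mapping qualities.
#' @return a data frame of class `read_set`.
#' @export
read_set <- function(start, end, strand, seq, mapq) {
  rs <- data.frame(start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), seq = toupper(as.character(seq)),
                   mapq = as.numeric(mapq), stringsAsFactors = FALSE)
  if (nrow(rs)) {
    if (any(rs$start >= rs$end)) stop("start must be < end", call. = FALSE)
    if (any(!rs$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
    if (any(nchar(rs$seq) != rs$end - rs$start))
      stop("fragment sequence length must equal end - start", call. = FALSE)
    if (any(grepl("[^ACGTN]", rs$seq)))
      stop("fragment sequences must be over {A,C,G,T,N}", call. = FALSE)
  }
  class(rs) <- c("read_set", "data.frame")
  rs
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""), ""))
}

#' Fragment a sequence into damaged ancient-DNA style reads
#'
#' Tiles a reference-length sequence with random fragments to a target mean
#' depth, then applies terminal cytosine-deamination damage: C->T at the 5'
#' end of each fragment (and, for double-stranded library simulation, G->A at
#' the 3' end) with per-position probability decaying geometrically from
#' `deamination_rate` at the terminal position. Fragment lengths are normal
#' around `frag_mean`; strands are assigned at random and damage is applied
#' in read orientation, so minus-strand fragments carry their damage at the
#' opposite reference ends.
#'
#' @param alignment_row a sequence string over `A C G T N` (one genome).
#' @param frag_mean,frag_sd fragment-length mean and SD in bp (ancient-DNA
#'   scale defaults, 60 +/- 15).
#' @param deamination_rate probability of C->T at the terminal position, in
#'   `[0, 1)`.
#' @param coverage target mean depth.
#' @param seed integer seed (mandatory).
#' @param double_stranded if `TRUE` (default) damage is C->T at 5' and G->A
#'   at 3'; if `FALSE` (single-stranded library) C->T at both ends.
#' @param decay geometric decay factor of the damage probability per position
#'   from the fragment end (default 0.5).
#' @param mapq mapping quality assigned to the simulated fragments.
#' @return a [read_set].
#' @export
degrade_to_reads <- function(alignment_row, frag_mean = 60, frag_sd = 15,
                             deamination_rate = 0, coverage = 5, seed,
                             double_stranded = TRUE, decay = 0.5, mapq = 37) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (deamination_rate < 0 || deamination_rate >= 1)
    stop("deamination_rate must be in [0, 1)", call. = FALSE)
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  ref <- toupper(alignment_row)
  L <- nchar(ref)
  set.seed(as.integer(seed))
  n_frag <- max(1L, round(coverage * L / frag_mean))
  lens <- pmin(L, pmax(1L, round(stats::rnorm(n_frag, frag_mean, frag_sd))))
  starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L, 0L)
  strands <- sample(c("+", "-"), n_frag, replace = TRUE)
  frags <- substring(ref, starts + 1L, starts + lens)

  if (deamination_rate > 0) {
    for (i in seq_len(n_frag)) {
      s <- frags[i]
      if (strands[i] == "-") s <- revcomp(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      l <- length(ch)
      p <- deamination_rate * decay^(seq_len(l) - 1L)       # from 5' end
      hit5 <- ch == "C" & stats::runif(l) < p
      ch[hit5] <- "T"
      p3 <- deamination_rate * decay^(rev(seq_len(l)) - 1L)  # from 3' end
      if (double_stranded) {
        hit3 <- ch == "G" & stats::runif(l) < p3
        ch[hit3] <- "A"
      } else {
        hit3 <- ch == "C" & stats::runif(l) < p3
        ch[hit3] <- "T"
      }
      s <- paste(ch, collapse = "")
      if (strands[i] == "-") s <- revcomp(s)
      frags[i] <- s
    }
  }
  read_set(starts, starts + lens, strands, frags, rep(mapq, n_frag))
}

#' Per-position base counts (pileup) from a read set
#'
#' Counts A, C, G, T at every reference position covered by the fragments;
#' `N` bases in reads contribute to no count. Depth at a position is the sum
#' of its four counts.
#'
#' @param reads a [read_set]; all fragments must lie within
#'   `[0, reference_length)`.
#' @param reference_length length of the reference in bp.
#' @return a `site_counts` data frame with columns `position` (0-based),
#'   `A`, `C`, `G`, `T`, `depth`, one row per reference position.
#' @export
make_pileup <- function(reads, reference_length) {
  L <- as.integer(reference_length)
  if (nrow(reads) && (min(reads$start) < 0L || max(reads$end) > L))
    stop("fragments must fall within [0, reference_length)", call. = FALSE)
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  if (nrow(reads)) {
    pos <- sequence(nvec = reads$end - reads$start, from = reads$start + 1L)
    base <- unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE)
    code <- match(base, BASES)  # NA for N
    keep <- !is.na(code)
    tab <- tabulate((pos[keep] - 1L) * 4L + code[keep], nbins = 4L * L)
    counts <- matrix(tab, nrow = L, ncol = 4L, byrow = TRUE,
                     dimnames = list(NULL, BASES))
  }
  sc <- data.frame(position = 0:(L - 1L), counts, depth = rowSums(counts))
  class(sc) <- c("site_counts", "data.frame")
  sc
}
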