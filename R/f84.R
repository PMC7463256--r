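#' F84 pairwise evolutionary distance
#'
#' The Felsenstein 1984 distance between two aligned sequences, allowing
#' unequal base frequencies and a transition/transversion bias. Sites where
#' either sequence has `N` or a gap are deleted pairwise before counting. With
#' transition proportion `P`, transversion proportion `Q`, and base
#' frequencies `pi`, the distance is
#' \deqn{d = -2A \log(1 - P/(2A) - (A - B)Q/(2AC)) + 2(A - B - C)\log(1 - Q/(2C))}
#' where `A = piC piT / piY + piA piG / piR`, `B = piC piT + piA piG`,
#' `C = piR piY`.
#'
#' By default the base frequencies are estimated from the two sequences
#' pooled (`freqs = "pair"`); alternatively a global frequency vector
#' estimated from a whole alignment can be supplied (`freqs = "global"`),
#' which is the convention of `ape::dist.dna`.
#'
#' Saturated pairs (non-positive logarithm arguments) and pairs with no
#' shared called sites are flagged by returning `NA` with an attribute
#' `reason` (`"saturated"` or `"no_sites"`); they are never clamped to a
#' number.
#'
#' @param seq_a,seq_b equal-length sequence strings over `A C G T N -`.
#' @param freqs `"pair"` (pooled over the two sequences) or `"global"`.
#' @param global_freqs length-4 simplex, required when `freqs = "global"`.
#' @return distance in substitutions/site, or `NA` with attribute `reason`.
#' @export
f84_distance <- function(seq_a, seq_b, freqs = c("pair", "global"),
                         global_freqs = NULL) {
  freqs <- match.arg(freqs)
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must have equal length", call. = FALSE)
  lut <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L, `-` = 4L)
  a <- lut[strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]]
  b <- lut[strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]]
  if (anyNA(a) || anyNA(b))
    stop("sequences contain characters outside {A,C,G,T,N,-}", call. = FALSE)
  keep <- a < 4L & b < 4L
  n <- sum(keep)
  if (n == 0L) return(undefined_distance("no_sites"))
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  purine_a <- a == 0L | a == 2L
  purine_b <- b == 0L | b == 2L
  P <- sum(diff & (purine_a == purine_b)) / n  # transitions
  Q <- sum(diff & (purine_a != purine_b)) / n  # transversions
  pi <- if (freqs == "pair") {
    counts <- tabulate(c(a, b) + 1L, nbins = 4L)
    counts / sum(counts)
  } else {
    if (is.null(global_freqs))
      stop("global_freqs required when freqs = 'global'", call. = FALSE)
    as.numeric(global_freqs)
  }
  if (any(pi == 0)) return(undefined_distance("degenerate_freqs"))
  piR <- pi[1L] + pi[3L]; piY <- pi[2L] + pi[4L]
  A <- pi[2L] * pi[4L] / piY + pi[1L] * pi[3L] / piR
  B <- pi[2L] * pi[4L] + pi[1L] * pi[3L]
  C <- piR * piY
  arg1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  arg2 <- 1 - Q / (2 * C)
  if (arg1 <= 0 || arg2 <= 0) return(undefined_distance("saturated"))
  d <- -2 * A * log(arg1) + 2 * (A - B - C) * log(arg2)
  structure(d, n_sites = n)
}

undefined_distance <- function(reason) {
  structure(NA_real_, reason = reason)
}

#' All pairwise F84 distances of an alignment
#'
#' Applies [f84_distance] to every unordered pair. Undefined entries are
#' propagated as `NA` (with the per-pair reasons collected in the
#' `"undefined"` attribute), never silently zeroed.
#'
#' @param alignment a [dna_alignment].
#' @param freqs `"pair"` or `"global"`; with `"global"`, the frequencies are
#'   the empirical frequencies of the whole alignment (as `ape::dist.dna`
#'   uses).
#' @return a symmetric matrix of distances with a zero diagonal, labelled by
#'   sequence id.
#' @export
distance_matrix <- function(alignment, freqs = c("pair", "global")) {
  freqs <- match.arg(freqs)
  gf <- if (freqs == "global") empirical_base_freqs(alignment) else NULL
  ids <- alignment$ids
  m <- length(ids)
  D <- matrix(0, m, m, dimnames = list(ids, ids))
  undef <- list()
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        d <- f84_distance(alignment$seqs[[i]], alignment$seqs[[j]],
                          freqs = freqs, global_freqs = gf)
        if (is.na(d))
          undef[[paste(ids[i], ids[j], sep = "|")]] <- attr(d, "reason")
        D[i, j] <- D[j, i] <- as.numeric(d)
      }
    }
  }
  attr(D, "undefined") <- undef
  D
}
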