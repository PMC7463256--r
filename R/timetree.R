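#' Rooted binary time-trees
#'
#' A `timetree` is a rooted, strictly binary genealogy whose nodes carry ages
#' in years before the youngest tip (time increases into the past). It wraps
#' the edge matrix of an [ape::phylo] object (tips numbered `1..n`, internal
#' nodes `n+1..2n-1`, root `n+1`) together with a single `ages` vector, so
#' that branch lengths are always derived as `age[parent] - age[child]` and
#' can never fall out of sync with the node ages.
#'
#' @param edge two-column integer matrix in `ape` edge format.
#' @param tip_labels character vector of tip labels, unique, length `n`.
#' @param ages numeric vector of node ages (years before the youngest tip),
#'   length `2n - 1`, indexed by node number.
#' @return An object of class `timetree`.
#' @export
timetree <- function(edge, tip_labels, ages) {
  edge <- matrix(as.integer(edge), ncol = 2L)
  n <- length(tip_labels)
  tr <- structure(
    list(edge = edge, tip_labels = as.character(tip_labels),
         ages = as.numeric(ages), n_tip = n),
    class = "timetree"
  )
  validate_timetree(tr)
  tr
}

validate_timetree <- function(tr) {
  n <- tr$n_tip
  if (n < 2L) stop("a timetree needs at least 2 tips", call. = FALSE)
  if (anyDuplicated(tr$tip_labels)) stop("tip labels must be unique", call. = FALSE)
  n_node <- 2L * n - 1L
  if (length(tr$ages) != n_node)
    stop("ages must have length 2*n_tip - 1", call. = FALSE)
  if (nrow(tr$edge) != n_node - 1L)
    stop("edge matrix must have 2*n_tip - 2 rows", call. = FALSE)
  if (any(!is.finite(tr$ages)) || any(tr$ages < 0))
    stop("node ages must be finite and non-negative", call. = FALSE)
  kids <- tabulate(tr$edge[, 1L], nbins = n_node)
  if (any(kids[(n + 1L):n_node] != 2L))
    stop("tree must be strictly binary (every internal node has 2 children)",
         call. = FALSE)
  par <- parent_vector(tr)
  root <- which(par == 0L)
  if (length(root) != 1L || root != n + 1L)
    stop("exactly one root required, numbered n_tip + 1", call. = FALSE)
  bad <- tr$ages[tr$edge[, 1L]] <= tr$ages[tr$edge[, 2L]]
  if (any(bad))
    stop("every parent must be strictly older than its children", call. = FALSE)
  invisible(tr)
}

#' @export
print.timetree <- function(x, ...) {
  cat("timetree with", x$n_tip, "tips\n")
  cat("  root age:", format(root_age(x)), "years before youngest tip\n")
  cat("  tip ages:", paste(format(tip_ages(x)), collapse = " "), "\n")
  invisible(x)
}

#' @rdname timetree
#' @param tr a `timetree`.
#' @export
tip_ages <- function(tr) {
  stats::setNames(tr$ages[seq_len(tr$n_tip)], tr$tip_labels)
}

#' @rdname timetree
#' @export
root_age <- function(tr) tr$ages[tr$n_tip + 1L]

## parent of each node (0 for the root)
parent_vector <- function(tr) {
  par <- integer(2L * tr$n_tip - 1L)
  par[tr$edge[, 2L]] <- tr$edge[, 1L]
  par
}

## list of children per internal node, as a 2-column matrix indexed by
## (node - n_tip)
children_matrix <- function(tr) {
  n <- tr$n_tip
  ch <- matrix(0L, nrow = n - 1L, ncol = 2L)
  fill <- integer(n - 1L)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L] - n
    fill[p] <- fill[p] + 1L
    ch[p, fill[p]] <- tr$edge[e, 2L]
  }
  ch
}

## internal nodes in postorder (children before parents)
postorder_nodes <- function(tr) {
  ord <- order(tr$ages[(tr$n_tip + 1L):(2L * tr$n_tip - 1L)])
  ord + tr$n_tip
}

#' Convert a timetree to an ape phylo object
#'
#' Branch lengths of the result are in years (`age[parent] - age[child]`).
#'
#' @param x a `timetree`.
#' @param ... unused.
#' @return an object of class `phylo`.
#' @export
as_phylo <- function(x, ...) UseMethod("as_phylo")

#' @export
as_phylo.timetree <- function(x, ...) {
  phy <- structure(
    list(edge = x$edge,
         edge.length = x$ages[x$edge[, 1L]] - x$ages[x$edge[, 2L]],
         tip.label = x$tip_labels,
         Nnode = x$n_tip - 1L),
    class = "phylo"
  )
  # establish a genuine cladewise edge ordering (edge rows from the
  # simulators are in event order, not traversal order)
  ape::reorder.phylo(phy, "cladewise")
}

#' Build a timetree from an ape phylo object
#'
#' Node ages are recomputed from root-to-node path lengths: branch lengths are
#' taken to be in years and the deepest tip is placed at age 0. If `tip_ages`
#' is supplied (a vector named by tip label, years before the youngest tip),
#' the recomputed ages are checked against it and the tree is shifted so the
#' named ages are honoured exactly; disagreement beyond `tol` (relative to the
#' root-to-tip depth) is an error, since it means the branch lengths and the
#' date table contradict each other.
#'
#' @param phy an [ape::phylo] with branch lengths in years.
#' @param tip_ages optional named numeric vector of tip ages.
#' @param tol relative tolerance for the branch-length/date consistency check.
#' @return a `timetree`.
#' @export
timetree_from_phylo <- function(phy, tip_ages = NULL, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("phy must be a phylo object", call. = FALSE)
  if (is.null(phy$edge.length)) stop("phy must have branch lengths", call. = FALSE)
  if (!ape::is.rooted(phy)) stop("tree must be rooted", call. = FALSE)
  if (!ape::is.binary(phy)) stop("tree contains polytomies; a strictly binary tree is required",
                                 call. = FALSE)
  phy <- ape::reorder.phylo(phy, "cladewise")
  n <- length(phy$tip.label)
  n_node <- 2L * n - 1L
  depth <- numeric(n_node)  # distance from root
  for (e in seq_len(nrow(phy$edge))) {  # cladewise order: parents first
    depth[phy$edge[e, 2L]] <- depth[phy$edge[e, 1L]] + phy$edge.length[e]
  }
  ages <- max(depth[seq_len(n)]) - depth
  if (!is.null(tip_ages)) {
    if (is.null(names(tip_ages)) || !all(phy$tip.label %in% names(tip_ages)))
      stop("tip_ages must be named and cover every tip", call. = FALSE)
    want <- as.numeric(tip_ages[phy$tip.label])
    got <- ages[seq_len(n)]
    shift <- stats::median(want - got)
    scale <- max(depth, 1)
    if (max(abs(got + shift - want)) > tol * scale)
      stop("branch lengths are inconsistent with the supplied tip ages",
           call. = FALSE)
    ages <- ages + shift
    ages[seq_len(n)] <- want
  }
  timetree(phy$edge, phy$tip.label, ages)
}

#' Most recent common ancestor of a set of tips
#'
#' @param tr a `timetree`.
#' @param labels character vector of two or more tip labels.
#' @return the internal node number of the MRCA.
#' @export
mrca_node <- function(tr, labels) {
  idx <- match(labels, tr$tip_labels)
  if (anyNA(idx)) stop("unknown tip label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  if (length(idx) < 2L) stop("need at least two tips for an MRCA", call. = FALSE)
  par <- parent_vector(tr)
  anc <- function(v) {
    out <- v
    while (par[v] != 0L) { v <- par[v]; out <- c(out, v) }
    out
  }
  common <- Reduce(intersect, lapply(idx, anc))
  common[which.min(tr$ages[common])]
}

## subset a timetree to a set of tip labels, preserving ages
keep_tips <- function(tr, labels) {
  phy <- as_phylo(tr)
  sub <- ape::keep.tip(phy, labels)
  ta <- tip_ages(tr)[labels]
  ta <- ta - min(ta)  # ages are relative to the youngest retained tip
  timetree_from_phylo(sub, tip_ages = ta)
}
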