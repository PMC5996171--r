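#' Read a rooted tree from a newick file
#'
#' Thin wrapper around \code{ape::read.tree} that tolerates quoted labels and
#' trees without branch lengths: absent or missing lengths are set to 1.0 with
#' a warning.
#'
#' @param path newick file path.
#' @return an \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using 1.0 for every branch")
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 1.0")
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  tree
}

#' Normalized weighted UniFrac distances
#'
#' For samples A and B with per-branch descendant abundance fractions
#' \eqn{A_b, B_b} and branch lengths \eqn{l_b},
#' \deqn{d(A, B) = \sum_b l_b |A_b - B_b| / \sum_b l_b (A_b + B_b),}
#' the normalized weighted UniFrac distance in [0, 1]. Counts are converted to
#' within-sample proportions first. Every table taxon must be a leaf of the
#' tree; extra leaves are allowed and carry zero weight.
#'
#' @param t a \code{feature_table} (or taxa-by-samples matrix with rownames).
#' @param tree a rooted \code{ape::phylo} with non-negative branch lengths.
#' @return a \code{dist} object over samples.
#' @export
weighted_unifrac <- function(t, tree) {
  m <- if (inherits(t, "feature_table")) t$counts else as.matrix(t)
  missing <- setdiff(rownames(m), tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  cs <- colSums(m)
  props <- sweep(m, 2, ifelse(cs == 0, 1, cs), "/")

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nsamp <- ncol(props)
  # per-node descendant abundance, accumulated in postorder
  acc <- matrix(0, nnode, nsamp)
  idx <- match(rownames(props), tree$tip.label)
  acc[idx, ] <- props
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    acc[parent, ] <- acc[parent, ] + acc[child, ]
  }
  ea <- acc[tr$edge[, 2], , drop = FALSE]  # branch x sample abundances
  len <- tr$edge.length

  d <- matrix(0, nsamp, nsamp, dimnames = list(colnames(props), colnames(props)))
  for (i in seq_len(nsamp - 1)) {
    for (j in seq(i + 1, nsamp)) {
      num <- sum(len * abs(ea[, i] - ea[, j]))
      den <- sum(len * (ea[, i] + ea[, j]))
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  stats::as.dist(d)
}
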