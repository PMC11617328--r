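#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that validates branch lengths and
#' warns when the tree is not ultrametric within a relative tolerance.
#'
#' @param text Newick string, or `NULL` to read from `file`.
#' @param file Path to a Newick file.
#' @param tol Relative tolerance on root-to-tip depth spread for the
#'   ultrametricity warning.
#' @return An object of class `"phylo"`.
#' @export
read_newick <- function(text = NULL, file = NULL, tol = 1e-6) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tr)) stop("read_newick: could not parse Newick input")
  if (anyDuplicated(tr$tip.label)) stop("read_newick: duplicate tip labels")
  if (is.null(tr$edge.length)) stop("read_newick: tree has no branch lengths")
  if (length(tr$tip.label) > 2 && !ape::is.ultrametric(tr, option = 2, tol = tol)) {
    warning("read_newick: tree is not ultrametric within tolerance ", tol)
  }
  tr
}

#' Root a tree at an outgroup taxon
#'
#' Places the root on the branch subtending `outgroup`, leaving the ingroup
#' topology untouched. Re-rooting at the current outgroup is a no-op.
#'
#' @param tree A `phylo` object.
#' @param outgroup Tip label to use as outgroup.
#' @return Rooted `phylo` object.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("root_at_outgroup: outgroup '", outgroup, "' is not a tip of the tree")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Replace zero-length branches with a small positive length
#'
#' Zero branch lengths make the Brownian-motion covariance singular; they
#' are raised to `epsilon` (default 0.00001). Strictly positive lengths are
#' untouched; negative lengths are an error.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param epsilon Replacement length for zero-length edges.
#' @return The repaired tree.
#' @export
repair_zero_branches <- function(tree, epsilon = 0.00001) {
  stopifnot(epsilon > 0)
  if (is.null(tree$edge.length)) stop("repair_zero_branches: tree has no branch lengths")
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    stop("repair_zero_branches: negative branch lengths at edges ",
         paste(neg, collapse = ", "))
  }
  tree$edge.length[tree$edge.length == 0] <- epsilon
  tree
}

#' Brownian-motion relatedness (phylogenetic correlation) matrix
#'
#' Entry (i, j) is the shared root-to-MRCA path length divided by the
#' root-to-tip depth, i.e. the Brownian-motion covariance normalized to
#' correlation form, so the diagonal is 1 for an ultrametric tree and the
#' phylogenetic variance component of the model sits on the same scale as
#' the other components.
#'
#' @param tree A rooted `phylo` object (outgroup already dropped).
#' @param species Character vector giving the species and their order for
#'   the rows/columns. Defaults to all tips.
#' @return Symmetric positive-semidefinite matrix with unit diagonal,
#'   dimnames = species.
#' @export
relatedness_matrix <- function(tree, species = tree$tip.label) {
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp)) {
    stop("relatedness_matrix: species not in tree: ",
         paste(missing_sp, collapse = ", "))
  }
  if (length(species) == 1) {
    return(matrix(1, 1, 1, dimnames = list(species, species)))
  }
  extra <- setdiff(tree$tip.label, species)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  V <- ape::vcv(tree, corr = FALSE)
  # correlation-normalize; for an ultrametric tree this divides by depth
  d <- sqrt(diag(V))
  A <- V / outer(d, d)
  diag(A) <- 1
  A <- (A + t(A)) / 2
  A[species, species, drop = FALSE]
}
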