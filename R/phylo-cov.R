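# Tree-derived covariance and Pagel-lambda transform.

#' Among-species covariance from a phylogeny
#'
#' Under Brownian trait evolution the covariance of two species equals the
#' shared branch length from the root to their most recent common ancestor;
#' the diagonal holds root-to-tip depths (constant for an ultrametric tree).
#'
#' @param tree A rooted `phylo` tree with branch lengths and >= 3 tips.
#' @return An object of class `phylo_covariance`: list with `species_order`,
#'   the matrix `C`, and `height` (maximum tip depth).
#' @export
phylo_covariance <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (ape::Ntip(tree) < 3) stop("tree must have >= 3 tips")
  # a basal polytomy (e.g. a star tree) is treated as a rooted polytomy
  if (all(tree$edge.length == 0)) stop("tree branch lengths are all zero")
  C <- ape::vcv.phylo(tree)
  structure(list(
    species_order = rownames(C),
    C = C,
    height = max(diag(C))
  ), class = "phylo_covariance")
}

#' @export
print.phylo_covariance <- function(x, ...) {
  cat("<phylo_covariance> ", length(x$species_order), " species, height ",
      format(x$height), "\n", sep = "")
  invisible(x)
}

as_cov_matrix <- function(C) {
  if (inherits(C, "phylo_covariance")) C$C
  else if (inherits(C, "phylo")) phylo_covariance(C)$C
  else as.matrix(C)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: lambda = 0 removes all phylogenetic covariance, lambda = 1
#' returns the Brownian expectation.
#'
#' @param C A `phylo_covariance`, `phylo` tree, or covariance matrix.
#' @param lambda Signal strength in `[0, 1]`.
#' @return A covariance matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  M <- as_cov_matrix(C)
  out <- M * lambda
  diag(out) <- diag(M)
  out
}

# Drop tips from a covariance structure, keeping the given species.
prune_covariance <- function(C, keep) {
  M <- as_cov_matrix(C)
  missing <- setdiff(keep, rownames(M))
  if (length(missing) > 0) {
    stop("species absent from phylogeny: ", paste(missing, collapse = ", "))
  }
  M[keep, keep, drop = FALSE]
}
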