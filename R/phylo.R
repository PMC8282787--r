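# Tree handling, multivariate Brownian-motion machinery, the phylogenetic
# (GLS) transformation and allometry correction.

#' Read and prune a Newick tree
#'
#' Reads a time-calibrated Newick tree and, when `species` is given, prunes
#' it to the intersection of tree tips and dataset species with a logged
#' report of what was dropped on either side.
#'
#' @param path Newick file path.
#' @param species optional character vector of analysis species.
#' @return an `ape::phylo` tree.
#' @export
read_newick_tree <- function(path, species = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(species)) {
    drop_tree <- setdiff(tree$tip.label, species)
    drop_data <- setdiff(species, tree$tip.label)
    if (length(drop_data))
      message("species absent from tree (dropped from analyses): ",
              paste(drop_data, collapse = ", "))
    if (length(drop_tree)) {
      message("tree tips not in dataset (pruned): ",
              paste(drop_tree, collapse = ", "))
      tree <- ape::drop.tip(tree, drop_tree)
    }
    if (ape::Ntip(tree) < 2L)
      stop("fewer than two species shared between tree and dataset")
  }
  tree
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip lengths.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return species x species covariance matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree) ape::vcv(tree)

#' Estimate a multivariate Brownian-motion model from tip data
#'
#' The per-unit-time trait rate matrix is the (REML) covariance of
#' branch-length-standardised phylogenetically independent contrasts; the
#' root state is the generalized-least-squares ancestral estimate under the
#' tree's Brownian covariance.
#'
#' @param tip_data species x D numeric matrix with species rownames.
#' @param tree phylogeny covering those species.
#' @param diagonal if `TRUE`, off-diagonal rates are zeroed.
#' @return object of class `bm_model` with `rate` (D x D symmetric PSD) and
#'   `root` (length-D GLS root state).
#' @export
estimate_bm_rates <- function(tip_data, tree, diagonal = FALSE) {
  tip_data <- as.matrix(tip_data)
  if (is.null(rownames(tip_data))) stop("tip_data needs species rownames")
  tip_data <- tip_data[tree$tip.label, , drop = FALSE]
  if (any(tree$edge.length[tree$edge[, 2] > ape::Ntip(tree)] <= 0))
    stop("zero-length internal branch: contrasts cannot be standardised")
  u <- apply(tip_data, 2, function(col) ape::pic(col, tree))
  u <- matrix(u, ncol = ncol(tip_data))
  rate <- crossprod(u) / nrow(u)
  if (diagonal) rate <- diag(diag(rate), nrow = nrow(rate))
  cinv <- solve(phylo_covariance(tree))
  one <- rep(1, nrow(tip_data))
  w <- as.numeric(cinv %*% one) / as.numeric(t(one) %*% cinv %*% one)
  root <- as.numeric(t(tip_data) %*% w)
  dimnames(rate) <- list(colnames(tip_data), colnames(tip_data))
  structure(list(rate = rate, root = root), class = "bm_model")
}

#' @export
print.bm_model <- function(x, ...) {
  cat("Brownian-motion model:", nrow(x$rate), "traits\n")
  cat("  rate diagonal:",
      paste(format(diag(x$rate), digits = 4), collapse = " "), "\n")
  invisible(x)
}

# symmetric PSD square root via eigendecomposition with an eigenvalue floor
.psd_sqrt <- function(m, floor = 0) {
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values), 1)))
    stop("matrix is not positive semidefinite")
  e$vectors %*% (sqrt(pmax(e$values, floor)) * t(e$vectors))
}

.inv_sqrt <- function(m, floor = 1e-12) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% ((1 / sqrt(vals)) * t(e$vectors))
}

#' Simulate multivariate Brownian motion on a tree
#'
#' Tip states accumulate Gaussian increments with covariance
#' `rate * branch_length` from root to tips; equivalently the tips follow a
#' matrix-normal distribution with among-species covariance `C` (the tree
#' covariance) and among-trait covariance `rate`, which is how draws are
#' generated here.
#'
#' @param tree phylogeny.
#' @param model a [estimate_bm_rates()] `bm_model` (or a list with `rate`
#'   and `root`).
#' @param n_sim number of replicate datasets.
#' @param seed integer seed (mandatory for reproducibility).
#' @return `n_sim` x n_species x D array with species dimnames.
#' @export
simulate_bm <- function(tree, model, n_sim = 1L, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  c_mat <- phylo_covariance(tree)
  lc <- .psd_sqrt(c_mat)
  lr <- .psd_sqrt(model$rate)
  n <- nrow(c_mat)
  d <- nrow(model$rate)
  out <- array(NA_real_, dim = c(n_sim, n, d),
               dimnames = list(NULL, rownames(c_mat), NULL))
  for (s in seq_len(n_sim)) {
    z <- matrix(stats::rnorm(n * d), n, d)
    out[s, , ] <- matrix(model$root, n, d, byrow = TRUE) + lc %*% z %*% lr
  }
  out
}

#' Phylogenetic (GLS) transformation of tip data
#'
#' Premultiplies data by the inverse square root of the tree covariance so
#' that ordinary cross-products on the transformed scale equal GLS
#' cross-products under Brownian motion. With `C = I` the input is returned
#' unchanged.
#'
#' @param tip_data species x D matrix with species rownames (or a plain
#'   matrix when `cov_matrix` is supplied in matching order).
#' @param tree phylogeny, or `NULL` when `cov_matrix` is given directly.
#' @param cov_matrix optional covariance matrix overriding the tree's.
#' @return transformed matrix with attribute `inv_sqrt` (the transform).
#' @export
pgls_transform <- function(tip_data, tree = NULL, cov_matrix = NULL) {
  tip_data <- as.matrix(tip_data)
  if (is.null(cov_matrix)) {
    if (is.null(tree)) stop("supply a tree or a covariance matrix")
    cov_matrix <- phylo_covariance(tree)
    tip_data <- tip_data[rownames(cov_matrix), , drop = FALSE]
  }
  if (rcond(cov_matrix) < 1e-14) stop("phylogenetic covariance is singular")
  p <- .inv_sqrt(cov_matrix)
  out <- p %*% tip_data
  rownames(out) <- rownames(tip_data)
  attr(out, "inv_sqrt") <- p
  out
}

#' Allometry correction by phylogenetic regression on size
#'
#' Residuals of the phylogenetic (GLS, Brownian-motion) regression of
#' flattened shape on size. The residuals are GLS-orthogonal to the size
#' covariate. By field convention the covariate is natural-log centroid
#' size (`log_size = TRUE`).
#'
#' @param shapes species x p matrix of shape variables (flattened aligned
#'   coordinates or PC scores) with species rownames.
#' @param sizes named numeric vector of centroid sizes per species.
#' @param tree phylogeny.
#' @param log_size log-transform the size covariate (default).
#' @return residual matrix (original, untransformed space) with attribute
#'   `coefficients` (2 x p GLS intercept/slope).
#' @export
allometry_residuals <- function(shapes, sizes, tree, log_size = TRUE) {
  shapes <- as.matrix(shapes)
  sp <- tree$tip.label
  shapes <- shapes[sp, , drop = FALSE]
  s <- sizes[sp]
  if (log_size) s <- log(s)
  if (stats::var(s) < 1e-16) {
    warning("size has zero variance; returning centred shapes")
    return(sweep(shapes, 2, colMeans(shapes)))
  }
  x <- cbind(1, s)
  cinv <- solve(phylo_covariance(tree))
  beta <- solve(t(x) %*% cinv %*% x, t(x) %*% cinv %*% shapes)
  res <- shapes - x %*% beta
  attr(res, "coefficients") <- beta
  res
}
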