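# Generalized Procrustes alignment, object-symmetry correction, species
# averaging and tangent-space PCA.

.centroid_size <- function(x) sqrt(sum(sweep(x, 2, colMeans(x))^2))

.center_config <- function(x) sweep(x, 2, colMeans(x))

# optimal proper rotation taking x onto target (both centred)
.rotate_onto <- function(x, target) {
  s <- svd(crossprod(x, target))
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {            # enforce det(R) = +1
    s$u[, ncol(s$u)] <- -s$u[, ncol(s$u)]
    r <- s$u %*% t(s$v)
  }
  x %*% r
}

.flatten <- function(arr) {
  # N x K x 3 array -> N x 3K matrix, landmark-major (x1 y1 z1 x2 ...)
  n <- dim(arr)[1]
  t(vapply(seq_len(n), function(i) as.vector(t(arr[i, , ])),
           numeric(dim(arr)[2] * 3L)))
}

.unflatten <- function(v, k) matrix(v, nrow = k, ncol = 3, byrow = TRUE)

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of landmark configurations: translate each to
#' the origin, optionally scale to unit centroid size, and rotate (proper
#' rotations only) onto the running consensus until the consensus changes by
#' less than `tol`.
#'
#' @param configs list of K x 3 matrices (identical K) or an N x K x 3 array.
#' @param scale if `TRUE` (full Procrustes, the default) configurations are
#'   scaled to unit centroid size; `FALSE` gives the partial-Procrustes
#'   variant.
#' @param tol convergence tolerance on the consensus change.
#' @param max_iter maximum number of alignment sweeps.
#' @param info optional data.frame of labels (one row per configuration),
#'   carried through to the result.
#' @return object of class `aligned_shapes`: `coords` (N x K x 3 array of
#'   aligned configurations), `centroid_size` (pre-scaling sizes),
#'   `consensus` (K x 3 mean shape), `info`, and the residual sum of squares
#'   trajectory `rss`.
#' @export
gpa <- function(configs, scale = TRUE, tol = 1e-10, max_iter = 100L,
                info = NULL) {
  if (is.array(configs) && length(dim(configs)) == 3L)
    configs <- lapply(seq_len(dim(configs)[1]), function(i) configs[i, , ])
  n <- length(configs)
  if (n < 2L) stop("need at least two configurations")
  k <- nrow(configs[[1]])
  if (!all(vapply(configs, nrow, integer(1)) == k))
    stop("all configurations must have the same number of landmarks")
  cs <- numeric(n)
  for (i in seq_len(n)) {
    x <- .center_config(configs[[i]])
    cs[i] <- sqrt(sum(x^2))
    if (cs[i] < 1e-12)
      stop("degenerate configuration ", i, ": centroid size is zero")
    configs[[i]] <- if (scale) x / cs[i] else x
  }
  consensus <- configs[[1]]
  rss <- numeric(0)
  for (iter in seq_len(max_iter)) {
    configs <- lapply(configs, .rotate_onto, target = consensus)
    new_cons <- Reduce(`+`, configs) / n
    if (scale) new_cons <- new_cons / sqrt(sum(new_cons^2))
    rss <- c(rss, sum(vapply(configs,
                             function(x) sum((x - new_cons)^2), numeric(1))))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (iter > 1L && delta < tol) break
  }
  arr <- array(NA_real_, dim = c(n, k, 3))
  for (i in seq_len(n)) arr[i, , ] <- configs[[i]]
  structure(list(coords = arr, centroid_size = cs, consensus = consensus,
                 info = info, rss = rss, scale = scale),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  d <- dim(x$coords)
  cat("Aligned shapes:", d[1], "configurations,", d[2], "landmarks\n")
  cat("  converged after", length(x$rss), "sweeps; final RSS",
      format(x$rss[length(x$rss)], digits = 6), "\n")
  invisible(x)
}

#' Procrustes distance between two aligned configurations
#'
#' Euclidean distance between two configurations in aligned coordinates.
#'
#' @param a,b K x 3 matrices.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Symmetric shape component under object symmetry
#'
#' Extracts the bilaterally symmetric component of each configuration: the
#' mirror of every configuration (first coordinate axis negated, left/right
#' landmarks relabelled) is included in a joint GPA with the originals, and
#' the symmetric shape is the average of each original and its relabelled
#' mirror. The asymmetric component (half-difference) is retained.
#'
#' @param configs list of K x 3 matrices or N x K x 3 array.
#' @param pairing a [landmark_pairing()].
#' @param mirror_axis coordinate axis negated to produce the mirror
#'   (default 1, the left-right axis of the digitising convention).
#' @param info optional label data.frame carried through.
#' @param ... passed to [gpa()].
#' @return an `aligned_shapes` object holding the symmetric component, with
#'   the asymmetric component in `$asymmetric`.
#' @export
symmetric_component <- function(configs, pairing, mirror_axis = 1L,
                                info = NULL, ...) {
  if (is.array(configs) && length(dim(configs)) == 3L)
    configs <- lapply(seq_len(dim(configs)[1]), function(i) configs[i, , ])
  k <- nrow(configs[[1]])
  if (pairing$k != k) stop("pairing does not match landmark count ", k)
  perm <- .pair_permutation(pairing)
  mirrors <- lapply(configs, function(x) {
    m <- x
    m[, mirror_axis] <- -m[, mirror_axis]
    m[perm, , drop = FALSE]
  })
  joint <- gpa(c(configs, mirrors), ...)
  n <- length(configs)
  sym <- array(NA_real_, dim = c(n, k, 3))
  asym <- array(NA_real_, dim = c(n, k, 3))
  for (i in seq_len(n)) {
    sym[i, , ] <- (joint$coords[i, , ] + joint$coords[n + i, , ]) / 2
    asym[i, , ] <- (joint$coords[i, , ] - joint$coords[n + i, , ]) / 2
  }
  consensus <- apply(sym, c(2, 3), mean)
  structure(list(coords = sym, centroid_size = joint$centroid_size[1:n],
                 consensus = consensus, info = info, rss = joint$rss,
                 scale = joint$scale, asymmetric = asym, pairing = pairing),
            class = "aligned_shapes")
}

#' Average aligned shapes within species
#'
#' Replaces the specimens of each (species, region, position) cell by their
#' landmark-wise arithmetic mean configuration; centroid sizes are averaged
#' likewise. Intraspecific variation is thereby removed before interspecific
#' analyses.
#'
#' @param aligned an `aligned_shapes` object whose `info` contains `species`,
#'   `region`, `position`.
#' @return an `aligned_shapes` object with one configuration per cell.
#' @export
average_by_species <- function(aligned) {
  info <- aligned$info
  if (is.null(info) || !all(c("species", "region", "position") %in% names(info)))
    stop("aligned$info must label species, region and position")
  key <- paste(info$species, info$region, info$position, sep = "\r")
  ukey <- unique(key)
  k <- dim(aligned$coords)[2]
  arr <- array(NA_real_, dim = c(length(ukey), k, 3))
  cs <- numeric(length(ukey))
  rows <- match(ukey, key)
  for (j in seq_along(ukey)) {
    idx <- which(key == ukey[j])
    m <- aligned$coords[idx[1], , ]
    if (length(idx) > 1L)
      for (i in idx[-1]) m <- m + aligned$coords[i, , ]
    arr[j, , ] <- m / length(idx)
    cs[j] <- mean(aligned$centroid_size[idx])
  }
  out_info <- info[rows, c("species", "region", "position"), drop = FALSE]
  out_info$label <- serial_label(out_info$region, out_info$position)
  rownames(out_info) <- NULL
  structure(list(coords = arr, centroid_size = cs,
                 consensus = apply(arr, c(2, 3), mean),
                 info = out_info, rss = aligned$rss, scale = aligned$scale),
            class = "aligned_shapes")
}

#' Tangent-space principal component analysis
#'
#' PCA of the flattened aligned coordinates (covariance eigendecomposition),
#' approximating shape space locally as Euclidean. Shape models along a
#' component are obtained as `mean + c * loading` reshaped to K x 3.
#'
#' @param aligned an `aligned_shapes` object (or an N x p numeric matrix).
#' @return object of class `tangent_pca`: `scores` (N x D, column-centred),
#'   `loadings` (D x p orthonormal rows), `variance_explained` (length D,
#'   non-increasing, sums to 1 over all non-zero components), `mean_shape`
#'   (K x 3 when shapes were supplied), and `center` (the p-vector mean).
#' @export
tangent_pca <- function(aligned) {
  if (inherits(aligned, "aligned_shapes")) {
    x <- .flatten(aligned$coords)
    k <- dim(aligned$coords)[2]
  } else {
    x <- as.matrix(aligned)
    k <- NULL
  }
  if (nrow(x) < 3L) stop("need at least 3 observations for PCA")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- p$sdev > max(p$sdev) * 1e-10
  structure(list(scores = p$x[, keep, drop = FALSE],
                 loadings = t(p$rotation[, keep, drop = FALSE]),
                 variance_explained = p$sdev[keep]^2 / sum(p$sdev^2),
                 center = p$center,
                 mean_shape = if (!is.null(k)) .unflatten(p$center, k),
                 info = if (inherits(aligned, "aligned_shapes")) aligned$info),
            class = "tangent_pca")
}

#' @export
print.tangent_pca <- function(x, ...) {
  ve <- x$variance_explained
  cat("Tangent-space PCA:", nrow(x$scores), "shapes,",
      length(ve), "components\n")
  cat("  PC1-PC3 variance:",
      paste(sprintf("%.1f%%", 100 * ve[seq_len(min(3, length(ve)))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Shape model along a principal component
#'
#' Reconstructs the configuration at `score` units along component `pc`
#' (e.g. the observed score range extremes of Fig.-style morphospace plots).
#'
#' @param pca a [tangent_pca()] result computed from shapes.
#' @param pc component index.
#' @param score displacement along the component.
#' @return K x 3 matrix.
#' @export
pc_shape_model <- function(pca, pc = 1L, score = 0) {
  if (is.null(pca$mean_shape)) stop("PCA was not computed from shapes")
  v <- pca$center + score * pca$loadings[pc, ]
  .unflatten(v, nrow(pca$mean_shape))
}
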