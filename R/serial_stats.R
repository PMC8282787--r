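# Within-region position ANOVAs and AR1 generalized least-squares
# comparisons of per-position metrics along the column.

#' Procrustes ANOVA of shape on serial position within a region
#'
#' Tests whether vertebral identity (position within region) structures
#' shape: a non-phylogenetic Procrustes ANOVA with position as a categorical
#' factor, rows being the species-level (or specimen-level) shapes of every
#' position in the region. The Z effect size quantifies how strongly
#' position explains morphology and is comparable across regions.
#'
#' @param aligned species-level `aligned_shapes` covering the region (or a
#'   list per region).
#' @param region `"cervical"`, `"thoracic"` or `"lumbar"`.
#' @param n_perm,seed permutation settings.
#' @return a [procrustes_anova()] object.
#' @export
position_anova <- function(aligned, region, n_perm = 999L, seed = NULL) {
  al <- if (inherits(aligned, "aligned_shapes")) aligned else aligned[[region]]
  idx <- which(al$info$region == region)
  if (!length(idx)) stop("no shapes for region ", region)
  pos <- factor(al$info$position[idx])
  if (nlevels(pos) < 2L) stop("need at least two positions in ", region)
  y <- .flatten(al$coords[idx, , , drop = FALSE])
  procrustes_anova(y, data.frame(position = pos), n_perm = n_perm,
                   seed = seed)
}

#' AR1 generalized least-squares regression along the column
#'
#' Fits `y ~ x` for per-position metric series by maximum likelihood with a
#' first-order autoregressive error structure, accounting for the serial
#' correlation of adjacent vertebral positions. ML (not REML) is used so
#' that models with different fixed effects are comparable. The slope
#' p-value is a t-test with n - 2 degrees of freedom.
#'
#' @param y,x numeric series aligned to the same ordered positions.
#' @param order integer or numeric position order (default: index order).
#'   Interior gaps are flagged with a warning.
#' @return object of class `serial_gls`: `slope`, `intercept`, `phi`,
#'   `slope_se`, `p_value`, `n`, `log_lik`, and the underlying `nlme::gls`
#'   fit (`NULL` in the degenerate zero-residual case).
#' @export
gls_ar1 <- function(y, x, order = seq_along(y)) {
  if (length(y) != length(x)) stop("y and x lengths differ: alignment error")
  if (length(y) < 4L) stop("need at least 4 positions")
  if (anyNA(y) || anyNA(x)) stop("missing values in series: alignment error")
  ord <- as.numeric(order)
  if (any(diff(sort(ord)) > 1.5 * stats::median(diff(sort(ord)))))
    warning("interior gap in position order")
  dat <- data.frame(y = y, x = x, pos = ord)
  dat <- dat[base::order(dat$pos), ]
  ols <- stats::lm(y ~ x, data = dat)
  if (stats::sigma(ols) < 1e-10 * max(stats::sd(y), 1e-300)) {
    # perfectly collinear input: residual variance at machine floor
    co <- stats::coef(ols)
    return(structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                          phi = 0, slope_se = 0,
                          p_value = .Machine$double.xmin,
                          n = nrow(dat), log_lik = Inf, fit = NULL),
                     class = "serial_gls"))
  }
  fit <- tryCatch(
    nlme::gls(y ~ x, data = dat,
              correlation = nlme::corAR1(form = ~pos), method = "ML"),
    error = function(e) stop("AR1 GLS did not converge: ",
                             conditionMessage(e)))
  tt <- summary(fit)$tTable
  phi <- stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE)
  structure(list(slope = unname(tt["x", "Value"]),
                 intercept = unname(tt["(Intercept)", "Value"]),
                 phi = unname(phi),
                 slope_se = unname(tt["x", "Std.Error"]),
                 p_value = unname(tt["x", "p-value"]),
                 n = nrow(dat), log_lik = as.numeric(stats::logLik(fit)),
                 fit = fit),
            class = "serial_gls")
}

#' @export
print.serial_gls <- function(x, ...) {
  cat(sprintf(
    "AR1 GLS (ML): slope = %.4g (SE %.3g, p = %.4g), phi = %.3f, n = %d\n",
    x$slope, x$slope_se, x$p_value, x$phi, x$n))
  invisible(x)
}

#' Serial column order for a seriation scheme
#'
#' By-number series: C03-C07, T01-T14, L01-L07 (26 positions; T15/T16 are
#' too sparsely sampled for the serial regressions). By-position series:
#' C03-C07, Tfirst, Tmid, Tdiaph, Tlast, Lfirst, Lmid, Llast.
#'
#' @param scheme `"by_number"` or `"by_position"`.
#' @return character vector of ordered group keys.
#' @export
serial_order <- function(scheme = c("by_number", "by_position")) {
  scheme <- match.arg(scheme)
  if (scheme == "by_number")
    c(serial_label("cervical", 3:7), serial_label("thoracic", 1:14),
      serial_label("lumbar", 1:7))
  else
    c(serial_label("cervical", 3:7), "Tfirst", "Tmid", "Tdiaph", "Tlast",
      "Lfirst", "Lmid", "Llast")
}

#' AR1-GLS comparisons among per-position metrics
#'
#' Fits the three serial regressions relating interspecific disparity,
#' constraint (MDI) and the strength of ecomorphological signal (best-model
#' R-squared) across ordered vertebral positions: disparity ~ MDI,
#' disparity ~ R2 and MDI ~ R2, each with AR1 errors along the column.
#'
#' @param disparity named per-position standardized disparities.
#' @param mdi_values named per-position MDI values.
#' @param ecology_r2 named per-position best-model R-squared values (groups
#'   with no admissible model contribute 0 signal).
#' @param order character vector of position keys defining the shared
#'   ordered index; all three series must cover it.
#' @return object of class `serial_comparison`: the three `serial_gls` fits
#'   and a summary data.frame.
#' @export
compare_metrics <- function(disparity, mdi_values, ecology_r2, order) {
  pick <- function(v, nm) {
    if (!all(order %in% names(v)))
      stop("series '", nm, "' does not cover the ordered index: missing ",
           paste(setdiff(order, names(v)), collapse = ", "))
    as.numeric(v[order])
  }
  d <- pick(disparity, "disparity")
  m <- pick(mdi_values, "mdi")
  r <- pick(ecology_r2, "ecology_r2")
  idx <- seq_along(order)
  fits <- list(disparity_vs_mdi = gls_ar1(d, m, idx),
               disparity_vs_r2 = gls_ar1(d, r, idx),
               mdi_vs_r2 = gls_ar1(m, r, idx))
  summary <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(comparison = nm, slope = f$slope, phi = f$phi,
               p_value = f$p_value, n = f$n)
  }))
  structure(list(fits = fits, summary = summary, order = order),
            class = "serial_comparison")
}

#' @export
print.serial_comparison <- function(x, ...) {
  cat("Serial AR1-GLS comparisons (", length(x$order), "positions )\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
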