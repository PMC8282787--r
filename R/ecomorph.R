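# Locomotor-capability coding, (phylogenetic) Procrustes ANOVA with
# residual-randomization permutation (RRPP), exhaustive capability-subset
# model selection and morphological deviation quantification.

#' Canonical capability order
#'
#' Fixed order of the five locomotor capabilities used for sequential sums
#' of squares and reporting.
#' @export
capability_names <- c("terrestrial", "cursorial", "arboreal",
                      "aquatic", "fossorial")

.capability_vocab <- c("terrestrial", "cursorial", "scansorial", "arboreal",
                       "semi-aquatic", "aquatic", "semi-fossorial",
                       "fossorial")

#' Encode a traditional locomotor category as capabilities
#'
#' Translates a single-category ecological classification into the
#' multivariate presence/absence capability coding: terrestrial capability
#' for any species that habitually walks on the ground (terrestrial,
#' cursorial, scansorial, semi-aquatic, semi-fossorial); arboreal for
#' arboreal/scansorial; aquatic for aquatic/semi-aquatic (fully aquatic taxa
#' such as pinnipeds lack terrestrial capability, semi-aquatic taxa such as
#' otters retain it); fossorial for fossorial/semi-fossorial. Cursorial
#' capability is a behavioural criterion (forelimb used primarily for
#' terrestrial locomotion): it is set for the "cursorial" category and for
#' species on an explicit override list, never inferred otherwise.
#'
#' @param category traditional category, one of `r paste(.capability_vocab, collapse=", ")`.
#' @param cursorial_override logical: force cursorial capability.
#' @return named integer vector over [capability_names].
#' @export
encode_capabilities <- function(category, cursorial_override = FALSE) {
  if (!category %in% .capability_vocab)
    stop("unknown ecological category: ", category)
  v <- stats::setNames(integer(5), capability_names)
  if (category %in% c("terrestrial", "cursorial", "scansorial",
                      "semi-aquatic", "semi-fossorial"))
    v["terrestrial"] <- 1L
  if (category %in% c("arboreal", "scansorial")) v["arboreal"] <- 1L
  if (category %in% c("aquatic", "semi-aquatic")) v["aquatic"] <- 1L
  if (category %in% c("fossorial", "semi-fossorial")) v["fossorial"] <- 1L
  if (category == "cursorial" || isTRUE(cursorial_override)) {
    v["cursorial"] <- 1L
    v["terrestrial"] <- 1L               # cursorial implies terrestrial
  }
  v
}

#' Build a species x capability matrix
#'
#' @param species character vector of species names.
#' @param category traditional category per species.
#' @param cursorial_override species to which cursorial capability is
#'   assigned behaviourally (configuration data, not code).
#' @return binary matrix species x 5, class `capability_matrix`.
#' @export
capability_matrix <- function(species, category,
                              cursorial_override = character()) {
  m <- t(vapply(seq_along(species), function(i)
    encode_capabilities(category[i],
                        species[i] %in% cursorial_override),
    stats::setNames(integer(5), capability_names)))
  rownames(m) <- species
  if (any(rowSums(m) < 1L)) stop("species with no capability")
  class(m) <- c("capability_matrix", class(m))
  m
}

# ---------------------------------------------------------------------------
# Procrustes ANOVA with RRPP

.term_matrix <- function(v) {
  if (is.factor(v) || is.character(v)) {
    f <- factor(v)
    if (nlevels(f) < 2L) stop("factor term has a single level")
    stats::model.matrix(~f)[, -1, drop = FALSE]
  } else {
    matrix(as.numeric(v), ncol = 1)
  }
}

.ss_fit <- function(q, y) sum((crossprod(q, y))^2)

#' Procrustes ANOVA with residual-randomization permutation
#'
#' Multivariate ANOVA on shape data using squared distances among fitted
#' values: sequential (hierarchical) sums of squares, with significance from
#' RRPP — for each term, residuals of the reduced model are permuted across
#' observations, added back to the reduced-model fitted values, and the term
#' statistic recomputed; the observed arrangement counts as one iteration.
#' The effect size Z is computed on log-transformed F. When a tree (or
#' covariance matrix) is given, data and design are premultiplied by the
#' inverse square root of the Brownian covariance, giving the phylogenetic
#' Procrustes ANOVA; on a star tree this reduces to the ordinary analysis.
#'
#' @param y n x p matrix of shape variables (rownames = species when a tree
#'   is used).
#' @param design data.frame of explanatory terms, fitted in column order
#'   (sequential SS is order-dependent).
#' @param tree optional phylogeny.
#' @param cov_matrix optional covariance matrix (overrides `tree`).
#' @param n_perm number of random permutations (default 999; the observed
#'   arrangement is counted in addition).
#' @param seed optional integer seed for the permutations.
#' @return object of class `procrustes_anova` with an ANOVA `table`
#'   (Df, SS, MS, Rsq, F, Z, Pr(>F) per term plus Residuals and Total),
#'   GLS/OLS `coefficients`, the term-to-coefficient map, and permutation
#'   details.
#' @export
procrustes_anova <- function(y, design, tree = NULL, cov_matrix = NULL,
                             n_perm = 999L, seed = NULL) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (!is.data.frame(design)) design <- as.data.frame(design)
  if (nrow(design) != n) stop("design rows must match shape rows")
  if (n_perm < 99L) warning("n_perm < 99 gives coarse p-values")
  if (!is.null(seed)) set.seed(seed)

  if (!is.null(tree) && is.null(cov_matrix)) {
    cov_matrix <- phylo_covariance(tree)
    if (is.null(rownames(y)) || !all(rownames(cov_matrix) %in% rownames(y)))
      stop("rownames of y must match tree tips")
    ord <- rownames(cov_matrix)
    y <- y[ord, , drop = FALSE]
    design <- design[match(ord, rownames(design)), , drop = FALSE]
    if (anyNA(design)) stop("design rownames must match tree tips")
  }
  p_trans <- if (!is.null(cov_matrix)) .inv_sqrt(cov_matrix) else NULL

  terms <- names(design)
  xs <- lapply(design, .term_matrix)
  x_seq <- vector("list", length(terms) + 1L)
  x_seq[[1]] <- matrix(1, n, 1)
  for (k in seq_along(terms)) x_seq[[k + 1]] <- cbind(x_seq[[k]], xs[[k]])

  tr <- function(m) if (is.null(p_trans)) m else p_trans %*% m
  yt <- tr(y)
  qs <- lapply(x_seq, function(x) {
    qd <- qr(tr(x))
    list(q = qr.Q(qd)[, seq_len(qd$rank), drop = FALSE], rank = qd$rank)
  })
  n_terms <- length(terms)
  rank_full <- qs[[n_terms + 1]]$rank
  df <- vapply(2:(n_terms + 1), function(k) qs[[k]]$rank - qs[[k - 1]]$rank,
               integer(1))
  if (any(df < 1L)) stop("term adds no estimable dimensions: ",
                         paste(terms[df < 1L], collapse = ", "))
  total_sq <- sum(yt^2)
  rss <- vapply(qs, function(qq) total_sq - .ss_fit(qq$q, yt), numeric(1))
  ss <- rss[-length(rss)] - rss[-1]
  ss_total <- rss[1]
  ss_res <- rss[n_terms + 1]
  df_res <- n - rank_full
  df_total <- n - 1L
  ms <- ss / df
  ms_res <- ss_res / df_res
  f_obs <- ms / ms_res

  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  f_perm <- matrix(NA_real_, n_perm, n_terms)
  q_full <- qs[[n_terms + 1]]$q
  for (k in seq_len(n_terms)) {
    q_red <- qs[[k]]$q
    q_ful <- qs[[k + 1]]$q
    fit_red <- q_red %*% crossprod(q_red, yt)
    e_red <- yt - fit_red
    for (i in seq_len(n_perm)) {
      yp <- fit_red + e_red[perms[[i]], , drop = FALSE]
      ss_k <- .ss_fit(q_ful, yp) - .ss_fit(q_red, yp)
      rss_f <- sum(yp^2) - .ss_fit(q_full, yp)
      f_perm[i, k] <- (ss_k / df[k]) / (rss_f / df_res)
    }
  }
  eps <- 1e-12
  p_val <- vapply(seq_len(n_terms), function(k)
    (1 + sum(f_perm[, k] >= f_obs[k] - eps)) / (n_perm + 1), numeric(1))
  z_val <- vapply(seq_len(n_terms), function(k) {
    lf <- log(pmax(c(f_perm[, k], f_obs[k]), 1e-300))
    s <- stats::sd(lf)
    if (s < 1e-12) 0 else (log(max(f_obs[k], 1e-300)) - mean(lf)) / s
  }, numeric(1))

  x_full <- x_seq[[n_terms + 1]]
  beta <- qr.coef(qr(tr(x_full)), yt)
  beta[is.na(beta)] <- 0
  col_term <- c("(Intercept)",
                rep(terms, vapply(xs, ncol, integer(1))))
  rownames(beta) <- col_term

  tab <- data.frame(
    Df = c(df, df_res, df_total),
    SS = c(ss, ss_res, ss_total),
    MS = c(ms, ms_res, NA),
    Rsq = c(ss / ss_total, ss_res / ss_total, NA),
    F = c(f_obs, NA, NA),
    Z = c(z_val, NA, NA),
    `Pr(>F)` = c(p_val, NA, NA),
    row.names = c(terms, "Residuals", "Total"), check.names = FALSE)
  structure(list(table = tab, coefficients = beta, terms = terms,
                 n = n, n_perm = n_perm, phylogenetic = !is.null(cov_matrix),
                 f_perm = f_perm),
            class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, digits = 4, ...) {
  cat(if (x$phylogenetic) "Phylogenetic Procrustes ANOVA"
      else "Procrustes ANOVA",
      sprintf("(RRPP, %d permutations)\n", x$n_perm))
  print(format(x$table, digits = digits), quote = FALSE)
  invisible(x)
}

#' @export
summary.procrustes_anova <- function(object, ...) object$table

#' Morphological deviation associated with a capability
#'
#' Euclidean (Procrustes) distance in the fitted space between the model's
#' mean shape for capability present and capability absent, holding other
#' terms constant: the norm of the capability's coefficient row. When a
#' [tangent_pca()] is supplied the deviation vector is back-projected to
#' landmark space and attached as attribute `shape_vector` (a K x 3
#' displacement field); the distance itself is unchanged because the
#' loadings are orthonormal.
#'
#' @param anova a fitted [procrustes_anova()].
#' @param capability term name present in the fitted design.
#' @param pca optional `tangent_pca` whose scores were the ANOVA data.
#' @return non-negative scalar deviation.
#' @export
group_deviation <- function(anova, capability, pca = NULL) {
  if (!capability %in% anova$terms)
    stop("capability not in the fitted design: ", capability)
  rows <- which(rownames(anova$coefficients) == capability)
  b <- anova$coefficients[rows, , drop = FALSE]
  dev <- sqrt(sum(b^2))
  if (!is.null(pca)) {
    d_used <- ncol(anova$coefficients)
    v <- as.vector(b %*% pca$loadings[seq_len(d_used), , drop = FALSE])
    attr(dev, "shape_vector") <- .unflatten(v, nrow(pca$mean_shape))
  }
  dev
}

# ---------------------------------------------------------------------------
# Exhaustive model selection over capability subsets

#' Exhaustive capability-subset model selection
#'
#' Fits a (phylogenetic) Procrustes ANOVA for every non-empty subset of the
#' varying capabilities (terms in the canonical [capability_names] order),
#' computes each model's total R-squared from hierarchical sums of squares,
#' and selects the model with the highest R-squared among those in which all
#' terms are at least marginally significant (p < `alpha`, default 0.1). If
#' no subset is admissible the selection is empty (no significant ecology),
#' which is a result, not an error.
#'
#' @param y n x p shape matrix.
#' @param capabilities binary species x capability matrix (columns reordered
#'   to canonical order; constant columns dropped with a message).
#' @param tree optional phylogeny for the phylogenetic version.
#' @param n_perm permutations per fit.
#' @param seed integer seed; each subset gets a deterministic derived seed.
#' @param alpha admissibility threshold on every term's p-value.
#' @return object of class `model_selection`: `chosen` (character vector,
#'   possibly empty), `r_squared`, `fit` (the chosen `procrustes_anova` or
#'   NULL), and `ledger` (one row per candidate subset).
#' @export
select_best_model <- function(y, capabilities, tree = NULL, n_perm = 999L,
                              seed = 1L, alpha = 0.1) {
  caps <- as.matrix(capabilities)
  keep <- intersect(capability_names, colnames(caps))
  caps <- caps[, keep, drop = FALSE]
  varying <- apply(caps, 2, function(v) length(unique(v)) > 1L)
  if (any(!varying))
    message("constant capabilities dropped: ",
            paste(colnames(caps)[!varying], collapse = ", "))
  caps <- caps[, varying, drop = FALSE]
  m <- ncol(caps)
  if (m < 1L) stop("no capability varies across species")
  subsets <- unlist(lapply(seq_len(m), function(sz)
    utils::combn(colnames(caps), sz, simplify = FALSE)), recursive = FALSE)
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    des <- as.data.frame(caps[, sub, drop = FALSE])
    rownames(des) <- rownames(caps)
    fit <- tryCatch(procrustes_anova(y, des, tree = tree, n_perm = n_perm,
                                     seed = seed + i),
                    error = function(e) NULL)   # aliased terms: not a model
    if (is.null(fit)) {
      rows[[i]] <- data.frame(subset = paste(sub, collapse = "+"),
                              n_terms = length(sub), r_squared = NA_real_,
                              max_p = NA_real_, admissible = FALSE)
      next
    }
    pv <- fit$table[sub, "Pr(>F)"]
    r2 <- sum(fit$table[sub, "Rsq"])
    fits[[i]] <- fit
    rows[[i]] <- data.frame(subset = paste(sub, collapse = "+"),
                            n_terms = length(sub), r_squared = r2,
                            max_p = max(pv),
                            admissible = all(pv < alpha))
  }
  ledger <- do.call(rbind, rows)
  adm <- which(ledger$admissible)
  if (length(adm)) {
    best <- adm[order(-ledger$r_squared[adm], ledger$n_terms[adm])][1]
    chosen <- subsets[[best]]
    fit <- fits[[best]]
    r2 <- ledger$r_squared[best]
  } else {
    chosen <- character()
    fit <- NULL
    r2 <- NA_real_
  }
  structure(list(chosen = chosen, r_squared = r2, fit = fit,
                 ledger = ledger, alpha = alpha),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  if (length(x$chosen))
    cat("Best model:", paste(x$chosen, collapse = " + "),
        sprintf("(R2 = %.3f, all terms p < %g)\n", x$r_squared, x$alpha))
  else
    cat("No admissible model (no capability reaches p <", x$alpha, ")\n")
  cat("Candidates evaluated:", nrow(x$ledger), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Per-group scan

.p_stratum <- function(p) {
  cut(p, breaks = c(0, 0.01, 0.05, 0.1, 1),
      labels = c("p<0.01", "p<0.05", "p<0.1", "ns"),
      include.lowest = TRUE)
}

#' Ecological scan across vertebral groups
#'
#' Runs, for every group, single-capability (phylogenetic) Procrustes ANOVAs
#' (the per-capability significance grid) and the exhaustive subset model
#' selection, optionally after excluding a set of species (e.g. aquatic
#' taxa). Capabilities that are constant within a group (for instance
#' "aquatic" after excluding aquatic species) are dropped from its
#' candidates. Groups reduced below `min_species` are skipped with a log
#' message.
#'
#' @param group_data named list of species x p matrices (one per group,
#'   species rownames).
#' @param capabilities binary species x capability matrix.
#' @param tree optional phylogeny (pruned per group).
#' @param exclude species to exclude from every group.
#' @param n_perm,seed permutation settings; each group/capability pair gets
#'   a deterministic derived seed.
#' @param min_species minimum species per group (default 3).
#' @return object of class `ecological_scan`: `grid` (group x capability
#'   p-values and significance strata) and `selection` (per-group
#'   `model_selection`).
#' @export
ecological_scan <- function(group_data, capabilities, tree = NULL,
                            exclude = character(), n_perm = 999L, seed = 1L,
                            min_species = 3L) {
  grid <- list()
  selection <- list()
  for (gi in seq_along(group_data)) {
    g <- names(group_data)[gi]
    y <- as.matrix(group_data[[gi]])
    sp <- setdiff(rownames(y), exclude)
    if (length(sp) < min_species) {
      message("group ", g, " skipped: only ", length(sp), " species")
      next
    }
    y <- y[sp, , drop = FALSE]
    caps <- as.matrix(capabilities)[sp, , drop = FALSE]
    gtree <- if (!is.null(tree)) ape::keep.tip(tree, sp) else NULL
    varying <- colnames(caps)[apply(caps, 2,
                                    function(v) length(unique(v)) > 1L)]
    for (cp in varying) {
      des <- data.frame(v = caps[, cp])
      names(des) <- cp
      rownames(des) <- sp
      fit <- procrustes_anova(y, des, tree = gtree, n_perm = n_perm,
                              seed = seed + 1000L * gi + match(cp, capability_names))
      grid[[length(grid) + 1L]] <-
        data.frame(group = g, capability = cp,
                   r_squared = fit$table[cp, "Rsq"],
                   p = fit$table[cp, "Pr(>F)"])
    }
    selection[[g]] <- suppressMessages(
      select_best_model(y, caps[, varying, drop = FALSE], tree = gtree,
                        n_perm = n_perm, seed = seed + 7919L * gi))
  }
  grid <- do.call(rbind, grid)
  grid$stratum <- .p_stratum(grid$p)
  structure(list(grid = grid, selection = selection, exclude = exclude),
            class = "ecological_scan")
}

#' @export
print.ecological_scan <- function(x, ...) {
  cat("Ecological scan:", length(x$selection), "groups")
  if (length(x$exclude)) cat(" (excluding", length(x$exclude), "species)")
  cat("\n")
  sig <- x$grid[x$grid$p < 0.1, ]
  cat(" capability effects at p<0.1:", nrow(sig), "of", nrow(x$grid),
      "cells\n")
  invisible(x)
}
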