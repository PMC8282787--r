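# Shared fixture builders and independent reference implementations.

rand_config <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(k * 3), k, 3)
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# exactly bilaterally symmetric configuration for a given pairing
sym_config <- function(pairing, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_pair <- nrow(pairing$paired)
  left <- cbind(abs(rnorm(n_pair)) + 0.2, rnorm(n_pair), rnorm(n_pair))
  right <- left
  right[, 1] <- -right[, 1]
  mid <- cbind(0, rnorm(length(pairing$midline)),
               rnorm(length(pairing$midline)))
  x <- matrix(0, pairing$k, 3)
  x[pairing$paired[, 1], ] <- left
  x[pairing$paired[, 2], ] <- right
  x[pairing$midline, ] <- mid
  x
}

# dataset with one random configuration per expected vertebra per species
make_small_dataset <- function(meta_df, seed = 1) {
  set.seed(seed)
  coords <- list(); info <- list()
  for (i in seq_len(nrow(meta_df))) {
    m <- meta_df[i, ]
    pos <- list(cervical = 3:7, thoracic = seq_len(m$n_thoracic),
                lumbar = seq_len(m$n_lumbar))
    for (r in names(pos)) for (j in pos[[r]]) {
      coords[[length(coords) + 1L]] <-
        rand_config(default_landmark_counts[[r]])
      info[[length(info) + 1L]] <- data.frame(
        specimen_id = paste0(m$species, "_01"), species = m$species,
        region = r, position = j, stringsAsFactors = FALSE)
    }
  }
  vertebra_dataset(coords, do.call(rbind, info))
}

# brute-force Procrustes variance: explicit deviation loop
brute_pv <- function(x, unbiased = FALSE) {
  x <- as.matrix(x)
  m <- colMeans(x)
  s <- 0
  for (i in seq_len(nrow(x))) s <- s + sum((x[i, ] - m)^2)
  s / (if (unbiased) nrow(x) - 1 else nrow(x))
}

# independent relative-disparity-through-time reference: explicit loops
# over pairwise distances and an edge-table walk for stem ages
ref_dtt <- function(tree, x) {
  pair_disp <- function(tips) {
    m <- x[tips, , drop = FALSE]
    if (nrow(m) < 2) return(0)
    s <- 0; cnt <- 0
    for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      s <- s + sum((m[i, ] - m[j, ])^2); cnt <- cnt + 1
    }
    s / cnt
  }
  bt <- ape::branching.times(tree)
  total <- pair_disp(tree$tip.label)
  nodes <- as.integer(names(bt))
  node_age <- as.numeric(bt)
  stem_age <- vapply(seq_along(nodes), function(i) {
    par <- tree$edge[tree$edge[, 2] == nodes[i], 1]
    if (length(par)) bt[[as.character(par)]] else node_age[i]
  }, numeric(1))
  cuts <- sort(node_age, decreasing = TRUE)
  out <- numeric(length(cuts))
  out[1] <- 1
  for (i in 2:length(cuts)) {
    vals <- numeric(0)
    for (j in seq_along(nodes)) {
      if (stem_age[j] >= cuts[i - 1] && node_age[j] < cuts[i - 1])
        vals <- c(vals, pair_disp(ape::extract.clade(tree, nodes[j])$tip.label))
    }
    out[i] <- if (length(vals)) mean(vals) / total else 0
  }
  list(times = 1 - cuts / max(bt), observed = out)
}

flatten_truth <- function(arr) {
  y <- t(sapply(seq_len(dim(arr)[1]), function(i) as.vector(t(arr[i, , ]))))
  rownames(y) <- dimnames(arr)[[1]]
  y
}
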