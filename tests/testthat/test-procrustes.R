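test_that("GPA is invariant to rigid motion and scaling of inputs", {
  x <- rand_config(12, seed = 3)
  y <- 2.5 * x %*% random_rotation(seed = 4) +
    matrix(c(5, -2, 1), 12, 3, byrow = TRUE)
  al <- gpa(list(x, y, x + 0.01 * rand_config(12, seed = 5)))
  expect_lt(procrustes_distance(al$coords[1, , ], al$coords[2, , ]), 1e-8)
  # aligned configurations are centred with unit centroid size
  for (i in 1:3) {
    expect_lt(max(abs(colMeans(al$coords[i, , ]))), 1e-8)
    expect_lt(abs(sqrt(sum(al$coords[i, , ]^2)) - 1), 1e-8)
  }
  # consensus equals the coordinate-wise mean up to its own rescaling
  cons_raw <- apply(al$coords, c(2, 3), mean)
  expect_lt(procrustes_distance(al$consensus,
                                cons_raw / sqrt(sum(cons_raw^2))), 1e-8)
})

test_that("GPA residual sum of squares never increases across sweeps", {
  set.seed(11)
  al <- gpa(lapply(1:10, function(i) rand_config(8)))
  expect_true(all(diff(al$rss) <= 1e-10))
})

test_that("without scaling, a pure size difference gives the closed-form distance", {
  x <- rand_config(9, seed = 6)
  x <- sweep(x, 2, colMeans(x))
  al <- gpa(list(x, 1.3 * x), scale = FALSE)
  expect_equal(procrustes_distance(al$coords[1, , ], al$coords[2, , ]),
               0.3 * sqrt(sum(x^2)), tolerance = 1e-8)
})

test_that("degenerate configurations are rejected", {
  expect_error(gpa(list(matrix(1, 5, 3), rand_config(5))), "degenerate")
})

pairing10 <- landmark_pairing(cbind(1:2, 3:4), 5:10, 10)

test_that("a symmetric configuration is a fixed point of symmetry correction", {
  xs <- lapply(1:4, function(i) sym_config(pairing10, seed = i))
  sym <- symmetric_component(xs, pairing10)
  plain <- gpa(xs)
  for (i in 1:4)
    expect_lt(procrustes_distance(sym$coords[i, , ], plain$coords[i, , ]),
              1e-9)
  # symmetric component lies in the reflection-invariant subspace
  perm <- serialmorph:::.pair_permutation(pairing10)
  for (i in 1:4) {
    m <- sym$coords[i, , ]
    mm <- m; mm[, 1] <- -mm[, 1]; mm <- mm[perm, ]
    al2 <- gpa(list(m, mm))
    expect_lt(procrustes_distance(al2$coords[1, , ], al2$coords[2, , ]), 1e-8)
  }
})

test_that("symmetry correction is idempotent", {
  xs <- lapply(1:3, function(i) sym_config(pairing10, seed = 10 + i) +
                 0.05 * rand_config(10))
  s1 <- symmetric_component(xs, pairing10)
  s2 <- symmetric_component(lapply(1:3, function(i) s1$coords[i, , ]),
                            pairing10)
  # identical shapes up to the joint alignment's overall orientation
  for (i in 1:3) {
    al <- gpa(list(s1$coords[i, , ], s2$coords[i, , ]))
    expect_lt(procrustes_distance(al$coords[1, , ], al$coords[2, , ]), 1e-7)
  }
})

test_that("an asymmetric landmark is averaged with its mirrored partner", {
  x <- sym_config(pairing10, seed = 42)
  left <- pairing10$paired[1, 1]
  pert <- x
  pert[left, 2] <- pert[left, 2] + 1e-3
  sym <- symmetric_component(list(pert, sym_config(pairing10, seed = 43)),
                             pairing10)
  # hand-built expectation in the input frame: average the configuration
  # with its reflected, relabelled copy, landmark by landmark
  perm <- serialmorph:::.pair_permutation(pairing10)
  mirr <- pert; mirr[, 1] <- -mirr[, 1]; mirr <- mirr[perm, ]
  expected <- (pert + mirr) / 2
  # the symmetric component must match this up to rigid alignment
  al <- gpa(list(sym$coords[1, , ], expected))
  expect_lt(procrustes_distance(al$coords[1, , ], al$coords[2, , ]), 1e-6)
})

test_that("species averaging is the arithmetic mean over specimens", {
  x <- rand_config(6, seed = 1); y <- rand_config(6, seed = 2)
  arr <- array(NA_real_, c(3, 6, 3))
  arr[1, , ] <- x; arr[2, , ] <- y; arr[3, , ] <- x + 1
  al <- structure(list(
    coords = arr, centroid_size = c(2, 4, 6),
    info = data.frame(species = c("A", "A", "B"), region = "lumbar",
                      position = 1L)), class = "aligned_shapes")
  avg <- average_by_species(al)
  expect_equal(dim(avg$coords)[1], 2L)
  expect_equal(avg$coords[1, , ], (x + y) / 2)
  expect_equal(avg$coords[2, , ], x + 1)       # singleton passes through
  expect_equal(avg$centroid_size, c(3, 6))
})

test_that("triplicate averaging shrinks specimen error about 1/sqrt(3)", {
  set.seed(99)
  truth <- rand_config(6)
  n_rep <- 200
  err1 <- err3 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    specs <- lapply(1:3, function(i) truth + matrix(rnorm(18, sd = 0.05), 6, 3))
    m3 <- Reduce(`+`, specs) / 3
    err1[r] <- sqrt(sum((specs[[1]] - truth)^2))
    err3[r] <- sqrt(sum((m3 - truth)^2))
  }
  expect_gt(mean(err1), mean(err3))
  expect_equal(mean(err3) / mean(err1), 1 / sqrt(3), tolerance = 0.12)
})

test_that("tangent PCA concentrates single-coordinate variation on PC1", {
  set.seed(5)
  base <- rand_config(5)
  arr <- array(NA_real_, c(12, 5, 3))
  for (i in 1:12) { m <- base; m[1, 1] <- m[1, 1] + rnorm(1); arr[i, , ] <- m }
  al <- structure(list(coords = arr, centroid_size = rep(1, 12),
                       info = NULL), class = "aligned_shapes")
  p <- tangent_pca(al)
  expect_gt(p$variance_explained[1], 0.999)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-10)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  # scores are column-centred
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
})

test_that("full-rank PCA scores preserve pairwise shape distances", {
  set.seed(8)
  x <- matrix(rnorm(10 * 9), 10, 9)
  p <- tangent_pca(x)
  expect_equal(as.matrix(dist(p$scores)), as.matrix(dist(x)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("shape models along a PC reconstruct the mean at score zero", {
  set.seed(9)
  arr <- array(rnorm(10 * 5 * 3, sd = 0.1), c(10, 5, 3))
  for (i in 1:10) arr[i, , ] <- arr[i, , ] + rand_config(5, seed = 1)
  al <- structure(list(coords = arr, centroid_size = rep(1, 10),
                       info = NULL), class = "aligned_shapes")
  p <- tangent_pca(al)
  expect_equal(pc_shape_model(p, 1, 0), p$mean_shape, tolerance = 1e-12)
})
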