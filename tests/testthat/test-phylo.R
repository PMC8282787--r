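test_that("Newick reading, pruning and path lengths behave analytically", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  tr <- read_newick_tree(f)
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:2]), c(1, 1))
  # round trip preserves topology and branch lengths
  f2 <- withr::local_tempfile(fileext = ".nwk")
  set.seed(1)
  tr5 <- ape::rtree(5)
  ape::write.tree(tr5, f2)
  back <- read_newick_tree(f2)
  expect_equal(ape::dist.nodes(back)[1:5, 1:5],
               ape::dist.nodes(tr5)[1:5, 1:5], tolerance = 1e-10)
  # pruning preserves induced tip-to-tip path lengths
  keep <- tr5$tip.label[1:3]
  pruned <- suppressMessages(read_newick_tree(f2, species = keep))
  expect_equal(ape::cophenetic.phylo(pruned)[keep, keep],
               ape::cophenetic.phylo(tr5)[keep, keep], tolerance = 1e-10)
})

test_that("phylogenetic covariance matches shared path lengths", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_covariance(t2)), diag(2))
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  c3 <- phylo_covariance(t3)
  expect_equal(c3["A", "B"], 1)
  expect_equal(c3["A", "C"], 0)
  expect_equal(unname(diag(c3)), rep(2, 3))
  # positive semidefinite over random trees
  set.seed(7)
  for (i in 1:5) {
    tr <- ape::rtree(12)
    ev <- eigen(phylo_covariance(tr), symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), -1e-10)
  }
})

test_that("rate estimation matches the closed form on a near-star tree", {
  eps <- 1e-9
  txt <- sprintf(
    "(((((A:1,B:%.10f):%.10f,C:%.10f):%.10f,D:%.10f):%.10f,E:%.10f):%.10f,F:%.10f);",
    1, eps, 1 + eps, eps, 1 + 2 * eps, eps, 1 + 3 * eps, eps, 1 + 4 * eps)
  star <- ape::read.tree(text = txt)
  set.seed(11)
  x <- cbind(rnorm(6), rnorm(6, sd = 2))
  rownames(x) <- star$tip.label
  fit <- estimate_bm_rates(x, star)
  # star phylogeny, depth 1: REML rate = ordinary sample covariance
  expect_equal(unname(fit$rate), unname(stats::cov(x)), tolerance = 1e-4)
  expect_equal(fit$root, unname(colMeans(x)), tolerance = 1e-4)
  # constant tip data -> zero rate
  const <- matrix(5, 6, 2, dimnames = list(star$tip.label, NULL))
  expect_lt(max(abs(estimate_bm_rates(const, star)$rate)), 1e-18)
})

test_that("Brownian simulation reproduces the analytic tip covariance", {
  t2 <- ape::read.tree(text = "(A:3,B:3);")
  model <- structure(list(rate = matrix(1.5), root = 0), class = "bm_model")
  sims <- simulate_bm(t2, model, n_sim = 5000, seed = 2)
  expect_equal(var(sims[, "A", 1] - sims[, "B", 1]), 2 * 1.5 * 3,
               tolerance = 0.08)
  # zero rate: all tips at the root state
  z <- simulate_bm(t2, structure(list(rate = matrix(0), root = 4),
                                 class = "bm_model"), n_sim = 3, seed = 3)
  expect_true(all(z == 4))
  # elementwise tip covariance converges to rate * C
  set.seed(4)
  tr <- ape::rtree(6)
  c_mat <- phylo_covariance(tr)
  sims6 <- simulate_bm(tr, structure(list(rate = matrix(2), root = 0),
                                     class = "bm_model"),
                       n_sim = 4000, seed = 5)
  emp <- cov(sims6[, , 1])
  expect_lt(max(abs(emp - 2 * c_mat[colnames(emp), colnames(emp)])),
            0.12 * 2 * max(c_mat))
  # reproducible given seed
  again <- simulate_bm(tr, structure(list(rate = matrix(2), root = 0),
                                     class = "bm_model"),
                       n_sim = 2, seed = 5)
  expect_identical(again, simulate_bm(tr, structure(
    list(rate = matrix(2), root = 0), class = "bm_model"),
    n_sim = 2, seed = 5))
})

test_that("rate recovery is consistent under simulation", {
  set.seed(6)
  tr <- ape::rphylo(64, 0.1, 0)
  truth <- structure(list(rate = diag(c(1, 3)), root = c(0, 0)),
                     class = "bm_model")
  sims <- simulate_bm(tr, truth, n_sim = 10, seed = 8)
  recovered <- sapply(1:10, function(i) {
    x <- sims[i, , ]
    rownames(x) <- tr$tip.label
    diag(estimate_bm_rates(x, tr)$rate)
  })
  expect_equal(rowMeans(recovered), c(1, 3), tolerance = 0.15)
})

test_that("the GLS transform is exact and reduces correctly", {
  set.seed(9)
  x <- matrix(rnorm(12), 6, 2)
  rownames(x) <- paste0("t", 1:6)
  # identity covariance: data unchanged
  same <- pgls_transform(x, cov_matrix = diag(6))
  expect_equal(unname(same[, ]), unname(x), ignore_attr = TRUE)
  # transform then inverse-transform is the identity
  tr <- ape::rtree(6)
  tr$tip.label <- rownames(x)
  tx <- pgls_transform(x, tr)
  p <- attr(tx, "inv_sqrt")
  expect_equal(unname(solve(p) %*% tx), unname(x[rownames(phylo_covariance(tr)), ]),
               tolerance = 1e-8)
  expect_error(pgls_transform(x, cov_matrix = matrix(1, 6, 6)), "singular")
})

test_that("allometry residuals are GLS-orthogonal to size", {
  set.seed(10)
  tr <- ape::rphylo(12, 0.1, 0)
  sizes <- setNames(exp(rnorm(12)), tr$tip.label)
  # pure allometry: residuals vanish
  b <- rnorm(4)
  shapes <- outer(log(sizes), b) + 2
  rownames(shapes) <- tr$tip.label
  res <- allometry_residuals(shapes, sizes, tr)
  expect_lt(max(abs(res)), 1e-8)
  # generic shapes: GLS orthogonality t(X) C^-1 res = 0
  shapes2 <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(tr$tip.label, NULL))
  res2 <- allometry_residuals(shapes2, sizes, tr)
  cinv <- solve(phylo_covariance(tr))
  xd <- cbind(1, log(sizes[rownames(cinv)]))
  expect_lt(max(abs(t(xd) %*% cinv %*% res2[rownames(cinv), ])), 1e-8)
  # zero size variance: warning, centred shapes returned
  expect_warning(
    cen <- allometry_residuals(shapes2, setNames(rep(2, 12), tr$tip.label), tr),
    "zero variance")
  expect_equal(cen, sweep(shapes2, 2, colMeans(shapes2)), ignore_attr = TRUE)
})

test_that("PGLS on an equal-depth star tree reduces to ordinary regression", {
  eps <- 1e-9
  txt <- sprintf(
    "(((((A:1,B:%.10f):%.10f,C:%.10f):%.10f,D:%.10f):%.10f,E:%.10f):%.10f,F:%.10f);",
    1, eps, 1 + eps, eps, 1 + 2 * eps, eps, 1 + 3 * eps, eps, 1 + 4 * eps)
  star <- ape::read.tree(text = txt)
  set.seed(12)
  sizes <- setNames(exp(rnorm(6)), star$tip.label)
  shapes <- matrix(rnorm(18), 6, 3, dimnames = list(star$tip.label, NULL))
  res_pgls <- allometry_residuals(shapes, sizes, star)
  res_ols <- residuals(lm(shapes ~ log(sizes)))
  expect_equal(unname(res_pgls[rownames(shapes), ]), unname(res_ols),
               tolerance = 1e-5)
})
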