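test_that("traditional categories map to the capability coding rules", {
  cases <- list(
    terrestrial    = c(1, 0, 0, 0, 0),
    cursorial      = c(1, 1, 0, 0, 0),
    scansorial     = c(1, 0, 1, 0, 0),
    arboreal       = c(0, 0, 1, 0, 0),
    "semi-aquatic" = c(1, 0, 0, 1, 0),   # otter-like: retains terrestrial
    aquatic        = c(0, 0, 0, 1, 0),   # pinniped-like: no terrestrial
    "semi-fossorial" = c(1, 0, 0, 0, 1),
    fossorial      = c(0, 0, 0, 0, 1))
  for (cat in names(cases))
    expect_equal(unname(encode_capabilities(cat)), cases[[cat]],
                 label = cat)
  expect_error(encode_capabilities("volant"), "unknown")
  # behavioural cursorial override implies terrestrial capability
  v <- encode_capabilities("terrestrial", cursorial_override = TRUE)
  expect_equal(unname(v[c("terrestrial", "cursorial")]), c(1, 1))
})

test_that("capability matrices satisfy the coding invariants", {
  set.seed(1)
  cats <- sample(c("terrestrial", "cursorial", "scansorial", "aquatic",
                   "semi-fossorial"), 30, replace = TRUE)
  m <- capability_matrix(sprintf("sp%02d", 1:30), cats,
                         cursorial_override = "sp01")
  expect_true(all(rowSums(m) >= 1))
  expect_true(all(m[m[, "cursorial"] == 1, "terrestrial"] == 1))
  expect_true(all(m %in% 0:1))
})

test_that("Procrustes ANOVA partitions variance exactly and detects strong effects", {
  set.seed(2)
  g <- factor(rep(1:3, each = 8))
  y <- matrix(rnorm(24 * 5), 24, 5)
  y[g == 2, 1] <- y[g == 2, 1] + 6
  y[g == 3, 2] <- y[g == 3, 2] + 6
  a <- procrustes_anova(y, data.frame(g = g), n_perm = 199, seed = 3)
  tab <- a$table
  expect_equal(tab["g", "Df"], 2)
  expect_equal(tab["Residuals", "Df"], 21)
  expect_equal(tab["Total", "Df"], 23)
  expect_equal(sum(tab[c("g", "Residuals"), "SS"]), tab["Total", "SS"],
               tolerance = 1e-10)
  expect_equal(sum(tab[c("g", "Residuals"), "Rsq"]), 1, tolerance = 1e-10)
  expect_gt(tab["g", "Rsq"], 0.5)
  expect_equal(tab["g", "Pr(>F)"], 1 / 200)   # observed counted in
  expect_gt(tab["g", "Z"], 2)
  # determinism under the seed
  b <- procrustes_anova(y, data.frame(g = g), n_perm = 199, seed = 3)
  expect_identical(a$table, b$table)
  expect_error(procrustes_anova(y, data.frame(g = factor(rep(1, 24)))),
               "single level")
  expect_warning(procrustes_anova(y, data.frame(g = g), n_perm = 50),
                 "n_perm")
})

test_that("a null grouping explains almost nothing", {
  set.seed(4)
  y <- matrix(rnorm(30 * 4), 30, 4)
  a <- procrustes_anova(y, data.frame(g = factor(rep(1:2, each = 15))),
                        n_perm = 199, seed = 5)
  expect_lt(a$table["g", "Rsq"], 0.2)
  expect_gt(a$table["g", "Pr(>F)"], 0.05)
})

test_that("phylogenetic ANOVA on an equal-depth star tree equals the ordinary one", {
  eps <- 1e-9
  parts <- paste0(sprintf("t%d:1", 2:8), collapse = ",")
  txt <- "(((((((t1:1,t2:1):0.000000001,t3:1):0.000000001,t4:1):0.000000001,t5:1):0.000000001,t6:1):0.000000001,t7:1):0.000000001,t8:1);"
  star <- ape::read.tree(text = txt)
  set.seed(6)
  y <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(star$tip.label, NULL))
  des <- data.frame(v = c(0, 0, 0, 0, 1, 1, 1, 1))
  rownames(des) <- star$tip.label
  ord <- procrustes_anova(y, des, n_perm = 199, seed = 7)
  phy <- procrustes_anova(y, des, tree = star, n_perm = 199, seed = 7)
  expect_equal(phy$table["v", "F"], ord$table["v", "F"], tolerance = 1e-4)
  expect_equal(phy$table["v", "Rsq"], ord$table["v", "Rsq"], tolerance = 1e-4)
  expect_equal(phy$table["v", "Pr(>F)"], ord$table["v", "Pr(>F)"],
               tolerance = 0.02)
})

test_that("sequential SS depends on term order but the total does not", {
  set.seed(8)
  n <- 40
  a_var <- rbinom(n, 1, 0.5)
  b_var <- ifelse(runif(n) < 0.7, a_var, rbinom(n, 1, 0.5))  # correlated
  y <- matrix(rnorm(n * 4), n, 4) + cbind(a_var * 2, b_var, 0, 0)
  f_ab <- procrustes_anova(y, data.frame(a = a_var, b = b_var),
                           n_perm = 99, seed = 9)
  f_ba <- procrustes_anova(y, data.frame(b = b_var, a = a_var),
                           n_perm = 99, seed = 9)
  expect_false(isTRUE(all.equal(f_ab$table["a", "SS"], f_ba$table["a", "SS"])))
  expect_equal(f_ab$table["a", "SS"] + f_ab$table["b", "SS"],
               f_ba$table["a", "SS"] + f_ba$table["b", "SS"],
               tolerance = 1e-10)
})

test_that("exhaustive selection covers all subsets and finds a strong effect", {
  set.seed(10)
  n <- 40
  caps <- sapply(capability_names, function(i) rbinom(n, 1, 0.4))
  caps[, "terrestrial"] <- pmax(caps[, "terrestrial"], caps[, "cursorial"])
  rownames(caps) <- sprintf("sp%02d", 1:n)
  while (any(apply(caps, 2, function(v) length(unique(v)) == 1L)))
    caps[1, ] <- 1 - caps[1, ]
  y <- matrix(rnorm(n * 6, sd = 0.5), n, 6)
  y[, 1] <- y[, 1] + 3 * caps[, "aquatic"]
  rownames(y) <- rownames(caps)
  sel <- select_best_model(y, caps, n_perm = 99, seed = 11)
  expect_equal(nrow(sel$ledger), 31L)     # 2^5 - 1 candidate subsets
  expect_true("aquatic" %in% sel$chosen)
  expect_true(all(sel$ledger$admissible %in% c(TRUE, FALSE)))
  # the chosen model maximises R^2 among admissible candidates
  adm <- sel$ledger[sel$ledger$admissible, ]
  expect_equal(sel$r_squared, max(adm$r_squared))
})

test_that("group deviation recovers an injected shift and is rotation-invariant", {
  set.seed(12)
  n <- 60
  cap <- rbinom(n, 1, 0.4)
  delta <- 0.5
  dir <- rnorm(8); dir <- dir / sqrt(sum(dir^2))
  y <- matrix(rnorm(n * 8, sd = 0.05), n, 8) + outer(cap * delta, dir)
  fit <- procrustes_anova(y, data.frame(cursorial = cap), n_perm = 99,
                          seed = 13)
  d <- group_deviation(fit, "cursorial")
  expect_equal(as.numeric(d), delta, tolerance = 0.1)
  # rotation of the shape space leaves the deviation unchanged
  q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  fit_rot <- procrustes_anova(y %*% q, data.frame(cursorial = cap),
                              n_perm = 99, seed = 13)
  expect_equal(as.numeric(group_deviation(fit_rot, "cursorial")),
               as.numeric(d), tolerance = 1e-8)
  expect_error(group_deviation(fit, "aquatic"), "not in the fitted design")
})

test_that("the ecological scan drops constant capabilities and is deterministic", {
  set.seed(14)
  n <- 20
  sp <- sprintf("sp%02d", 1:n)
  caps <- capability_matrix(sp, sample(c("terrestrial", "aquatic",
                                         "scansorial"), n, replace = TRUE,
                                       prob = c(0.5, 0.25, 0.25)))
  tr <- ape::rphylo(n, 0.1, 0); tr$tip.label <- sp
  gd <- list(g1 = matrix(rnorm(n * 5), n, 5, dimnames = list(sp, NULL)),
             g2 = matrix(rnorm(n * 5), n, 5, dimnames = list(sp, NULL)))
  aq <- sp[caps[, "aquatic"] == 1]
  s1 <- suppressMessages(ecological_scan(gd, caps, tr, exclude = aq,
                                         n_perm = 99, seed = 15))
  expect_false("aquatic" %in% s1$grid$capability)
  s2 <- suppressMessages(ecological_scan(gd, caps, tr, exclude = aq,
                                         n_perm = 99, seed = 15))
  expect_identical(s1$grid, s2$grid)
  # groups below the species minimum are skipped with a message
  gd$tiny <- gd$g1[1:2, ]
  expect_message(
    suppressWarnings(ecological_scan(gd, caps, tr, n_perm = 99, seed = 16)),
    "skipped")
})
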