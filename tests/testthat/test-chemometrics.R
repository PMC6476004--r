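test_that("PCA reproduces the covariance eigen-decomposition", {
  set.seed(21)
  X <- matrix(rnorm(24), 6, 4)
  m <- fit_pca(X, n_components = 3, scaling = "center")
  ev <- eigen(cov(X), symmetric = TRUE)
  # eigenvalues: singular values squared over n - 1
  expect_equal(diag(crossprod(m$scores)) / (nrow(X) - 1),
               setNames(ev$values[1:3], colnames(m$scores)),
               tolerance = 1e-8)
  for (a in 1:3) {
    expect_equal(abs(sum(m$loadings[, a] * ev$vectors[, a])), 1,
                 tolerance = 1e-8)
  }
  # score orthogonality and non-increasing explained variance
  off <- crossprod(m$scores)
  expect_true(all(abs(off[upper.tri(off)]) < 1e-8))
  expect_true(all(diff(m$r2x_per_component) <= 1e-12))
})

test_that("PCA handles rank-1, duplicated-row and degenerate inputs", {
  u <- c(1, 2, 3, 4, 5)
  X <- outer(u, c(2, -1, 0.5))
  m <- fit_pca(X, n_components = 1, scaling = "center")
  expect_equal(m$r2x, 1, tolerance = 1e-12)

  set.seed(22)
  Xd <- matrix(rnorm(20), 5, 4)[c(1, 1, 2, 3, 4), ]
  md <- fit_pca(Xd, n_components = 2, scaling = "center")
  expect_equal(md$scores[1, ], md$scores[2, ], tolerance = 1e-10)

  expect_error(fit_pca(matrix(3, 4, 3)), class = "nmrmet_fit_error")
})

test_that("PLS-DA first weight vector is proportional to X'y", {
  set.seed(23)
  X <- matrix(rnorm(60), 10, 6)
  g <- rep(c("a", "b"), each = 5)
  m <- fit_plsda(X, g, n_components = 2, scaling = "center", cv = FALSE)
  yc <- as.numeric(g == "b") - 0.5
  Xc <- scale(X, scale = FALSE)
  w_direct <- drop(crossprod(Xc, yc))
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  expect_equal(unname(m$weights[, 1]), w_direct, tolerance = 1e-10)
})

test_that("a perfectly ordered single variable yields a high Q2", {
  x <- matrix(c(1:14, 31:44), ncol = 1)
  g <- rep(c("a", "b"), each = 14)
  m <- fit_plsda(x, g, n_components = 1)
  expect_gt(m$q2, 0.9)
})

test_that("degenerate class structures are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_plsda(X, rep("a", 10)), class = "nmrmet_fit_error")
  expect_error(fit_plsda(X, c("a", rep("b", 9))), class = "nmrmet_fit_error")
  expect_error(fit_oplsda(X, rep(c("a", "b", "c"), c(4, 3, 3))),
               class = "nmrmet_fit_error")
})

test_that("OPLS-DA with no orthogonal component equals 1-component PLS-DA", {
  set.seed(24)
  X <- matrix(rnorm(200), 20, 10)
  g <- rep(c("a", "b"), each = 10)
  X[g == "b", 1:3] <- X[g == "b", 1:3] + 1
  o <- fit_oplsda(X, g, n_orth = 0, cv = FALSE)
  p <- fit_plsda(X, g, n_components = 1, cv = FALSE)
  expect_equal(unname(o$scores[, 1]), unname(p$scores[, 1]), tolerance = 1e-8)
  expect_equal(unname(o$weights[, 1]), unname(p$weights[, 1]),
               tolerance = 1e-8)
  expect_equal(o$r2y, p$r2y, tolerance = 1e-8)
})

test_that("OPLS-DA separates a planted class direction from a confounder", {
  set.seed(25)
  n <- 40
  p <- 30
  g <- rep(c("a", "b"), each = n / 2)
  y <- as.numeric(g == "b")
  d <- rnorm(p)
  d <- d / sqrt(sum(d^2))
  conf <- rnorm(p)
  conf <- conf - sum(conf * d) * d
  conf <- conf / sqrt(sum(conf^2))
  X <- outer(y - 0.5, d) * 4 + outer(rnorm(n, sd = 4), conf) +
    matrix(rnorm(n * p, sd = 0.2), n, p)
  m <- fit_oplsda(X, g, n_orth = 1, scaling = "center", cv = FALSE)
  w <- m$weights[, 1]
  expect_gt(abs(sum(w * d)) / sqrt(sum(w^2)), 0.95)
  # orthogonal scores have zero covariance with the class vector
  yc <- y - mean(y)
  expect_lt(max(abs(crossprod(m$orth_scores, yc))), 1e-8)
  # predictive score orientation: second class has positive mean tp1
  expect_gt(mean(m$scores[g == "b", 1]), 0)
})

test_that("cross-validation attains Q2 = 1 for a perfectly predictive X", {
  g <- rep(c("a", "b"), each = 7)
  x <- matrix(as.numeric(g == "b"), ncol = 1) # X literally encodes y
  q2 <- cross_validate(x, g, method = "plsda", n_components = 1)
  expect_equal(as.numeric(q2), 1, tolerance = 1e-9)
})

test_that("cross-validation is seeded, stratified and guards fold counts", {
  set.seed(26)
  X <- matrix(rnorm(28 * 5), 28, 5)
  g <- rep(c("a", "b"), each = 14)
  expect_identical(cross_validate(X, g, seed = 3), cross_validate(X, g, seed = 3))
  expect_error(cross_validate(X, g, k = 15), class = "nmrmet_fold_error")
  expect_error(cross_validate(X, g, k = 1), class = "nmrmet_fold_error")
})

test_that("pure-noise data yields non-positive mean Q2", {
  set.seed(27)
  q2 <- vapply(1:60, function(i) {
    X <- matrix(rnorm(40 * 10), 40, 10)
    g <- rep(c("a", "b"), each = 20)
    as.numeric(cross_validate(X, g, seed = i))
  }, numeric(1))
  expect_lte(mean(q2), 0)
})

test_that("permutation testing reports the observed model and exact p under signal", {
  set.seed(28)
  X <- matrix(rnorm(28 * 8), 28, 8)
  g <- rep(c("a", "b"), each = 14)
  X[g == "b", 1:4] <- X[g == "b", 1:4] + 3
  pt <- permutation_test(X, g, n_perm = 49, seed = 5)
  obs <- pt$permutations[pt$permutations$observed, ]
  m <- fit_oplsda(X, g, cv_folds = 7, cv_seed = 5)
  expect_equal(obs$r2y, m$r2y, tolerance = 1e-10)
  expect_equal(obs$q2, as.numeric(m$q2), tolerance = 1e-10)
  expect_equal(obs$correlation, 1)
  # a strong planted effect beats every permutation
  expect_equal(pt$empirical_p, 1 / 50)
  expect_lt(pt$rpt_intercepts["q2_intercept"], pt$observed["q2"])
  expect_error(permutation_test(X, g, n_perm = 5),
               class = "nmrmet_config_error")
})

test_that("CV-ANOVA yields tiny p for perfect prediction and F >= 0 always", {
  g <- rep(c("a", "b"), each = 7)
  x <- matrix(as.numeric(g == "b"), ncol = 1)
  ca <- cv_anova(x, g, method = "plsda", n_components = 1)
  expect_lt(ca$p, 1e-10)

  set.seed(29)
  saw_null <- FALSE
  for (i in 1:8) {
    X <- matrix(rnorm(30 * 12), 30, 12)
    gg <- rep(c("a", "b"), each = 15)
    ca <- cv_anova(X, gg, seed = i)
    expect_gte(ca$F, 0)
    expect_lte(ca$p, 1)
    q2 <- as.numeric(cross_validate(X, gg, seed = i))
    if (q2 <= 0) {
      saw_null <- TRUE
      expect_equal(ca$p, 1) # PRESS >= SS never counts as significant
    }
  }
  expect_true(saw_null)
})

test_that("VIP matches the direct formula and its normalization identity", {
  # 3-variable toy, 1 predictive component: VIP_j = sqrt(p) * |w_j|
  set.seed(30)
  X <- matrix(rnorm(24), 8, 3)
  g <- rep(c("a", "b"), each = 4)
  m <- fit_plsda(X, g, n_components = 1, scaling = "center", cv = FALSE)
  yc <- as.numeric(g == "b") - 0.5
  w_manual <- drop(crossprod(scale(X, scale = FALSE), yc))
  w_manual <- w_manual / sqrt(sum(w_manual^2))
  expect_equal(vip(m)$vip, sqrt(3) * abs(w_manual), tolerance = 1e-10)

  # identical copies of one signal -> all VIP exactly 1
  sig <- rnorm(10)
  Xc <- cbind(sig, sig, sig, sig)
  mc <- fit_plsda(Xc, rep(c("a", "b"), each = 5), n_components = 1,
                  cv = FALSE)
  expect_equal(vip(mc)$vip, rep(1, 4), tolerance = 1e-9)

  # mean(VIP^2) = 1 on arbitrary two-component fits
  set.seed(31)
  Xr <- matrix(rnorm(20 * 7), 20, 7)
  mr <- fit_plsda(Xr, rep(c("a", "b"), each = 10), n_components = 2,
                  cv = FALSE)
  expect_equal(mean(vip(mr)$vip^2), 1, tolerance = 1e-9)

  expect_error(vip(fit_pca(Xr, 2)), class = "nmrmet_type_error")
})

test_that("correlation loadings equal brute-force Pearson correlations", {
  set.seed(32)
  X <- matrix(rnorm(50), 10, 5)
  g <- rep(c("a", "b"), each = 5)
  X[, 5] <- 2 # zero variance
  m <- fit_oplsda(X, g, n_orth = 0, cv = FALSE)
  rl <- correlation_loadings(m)
  tp1 <- m$scores[, 1]
  for (j in 1:4) {
    num <- sum((X[, j] - mean(X[, j])) * (tp1 - mean(tp1)))
    den <- sqrt(sum((X[, j] - mean(X[, j]))^2) * sum((tp1 - mean(tp1))^2))
    expect_equal(rl$r[j], num / den, tolerance = 1e-12)
  }
  expect_true(all(abs(rl$r) <= 1 + 1e-12))
  expect_equal(rl$r[5], 0)
  expect_true(rl$zero_variance[5])
  # a variable equal to +/- tp1 correlates at exactly +/- 1
  m_hack <- m
  m_hack$X <- cbind(a = m$scores[, 1], b = -m$scores[, 1])
  r2 <- correlation_loadings(m_hack)$r
  expect_equal(r2[1], 1, tolerance = 1e-12)
  expect_equal(r2[2], -1, tolerance = 1e-12)
})

test_that("tidy and glance views expose scores and fit summaries", {
  set.seed(33)
  X <- matrix(rnorm(80), 16, 5)
  g <- rep(c("a", "b"), each = 8)
  m <- fit_oplsda(X, g, cv_folds = 4)
  gl <- glance(m)
  expect_named(gl, c("kind", "n_components", "n_orth", "r2x", "r2y", "q2",
                     "scaling"))
  td <- tidy(m)
  expect_equal(nrow(td), 16)
  expect_true(all(c("sample_id", "component", "score") %in% names(td)))
})
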