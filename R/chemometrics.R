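#' Latent-variable models for binned NMR data
#'
#' @name chemometrics
#' @keywords internal
NULL

# Resolve x into an active data matrix plus metadata. Accepts nmr_binned
# (masked bins are dropped, never zero-filled), a plain matrix or a data
# frame of numeric variables.
resolve_x <- function(x, group = NULL) {
  if (inherits(x, "nmr_binned")) {
    list(X = active_matrix(x),
         group = x$groups,
         sample_id = x$sample_id,
         variable_ppm = x$bin_centers[!x$excluded])
  } else {
    X <- as.matrix(x)
    if (!is.numeric(X)) {
      abort("x must be numeric", class = "nmrmet_fit_error")
    }
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    list(X = X, group = group,
         sample_id = rownames(X) %||% paste0("s", seq_len(nrow(X))),
         variable_ppm = NULL)
  }
}

# mean-centre + scale columns; SIMCA-style unit variance is the default,
# Pareto and centre-only available
scale_columns <- function(X, scaling = c("uv", "pareto", "center")) {
  scaling <- match.arg(scaling)
  ctr <- colMeans(X)
  Xc <- X - rep(ctr, each = nrow(X))
  s <- sqrt(colSums(Xc^2) / max(nrow(X) - 1, 1))
  sc <- switch(scaling,
    uv = ifelse(s > 0, s, 1),
    pareto = ifelse(s > 0, sqrt(s), 1),
    center = rep(1, ncol(X))
  )
  list(X = Xc / rep(sc, each = nrow(X)), center = ctr, scale = sc,
       scaling = scaling)
}

encode_y <- function(group) {
  g <- droplevels(factor(group))
  if (nlevels(g) != 2) {
    abort("exactly two classes are required (pairwise comparisons)",
          class = "nmrmet_fit_error")
  }
  if (any(table(g) < 2)) {
    abort("each class needs at least 2 samples", class = "nmrmet_fit_error")
  }
  # second class (alphabetical level order) coded 1 -> positive mean tp1
  list(y = as.numeric(g == levels(g)[2]), levels = levels(g), group = g)
}

new_latent <- function(...) structure(list(...), class = "nmr_latent")

#' Principal component analysis of a binned matrix
#'
#' Mean-centred (and scaled) singular value decomposition with components
#' ordered by explained variance and a deterministic sign convention (the
#' largest-magnitude loading element of each component is positive).
#'
#' @param x An `nmr_binned` object, matrix or data frame.
#' @param n_components Number of components (at most `min(n - 1, p)`).
#' @param scaling `"uv"` (default), `"pareto"` or `"center"`.
#' @return An `nmr_latent` model with scores, loadings and per-component
#'   `r2x`.
#' @export
fit_pca <- function(x, n_components = 3, scaling = "uv") {
  rx <- resolve_x(x)
  sc <- scale_columns(rx$X, scaling)
  X <- sc$X
  if (all(abs(X) < 1e-12)) {
    abort("matrix has zero variance everywhere", class = "nmrmet_fit_error")
  }
  kmax <- min(nrow(X) - 1, ncol(X))
  if (n_components > kmax) {
    abort(sprintf("n_components must be <= min(n - 1, p) = %d", kmax),
          class = "nmrmet_fit_error")
  }
  sv <- svd(X, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v
  for (a in seq_len(n_components)) {
    if (loadings[which.max(abs(loadings[, a])), a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  ssx <- sum(X^2)
  r2x_comp <- sv$d[seq_len(n_components)]^2 / ssx
  dimnames(scores) <- list(rx$sample_id, paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(rx$X), paste0("PC", seq_len(n_components)))
  new_latent(
    kind = "pca", scores = scores, loadings = loadings, weights = NULL,
    r2x = sum(r2x_comp), r2x_per_component = r2x_comp, r2y = NA_real_,
    q2 = NA_real_, n_components = n_components, n_orth = 0L,
    scaling = sc$scaling, center = sc$center, scale = sc$scale,
    sample_id = rx$sample_id, group = rx$group, y = NULL,
    variable_ppm = rx$variable_ppm, X = rx$X
  )
}

# PLS1 core (NIPALS, direct per-component solution for a single y)
pls1_core <- function(X, y, n_components) {
  p <- ncol(X)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(X), n_components)
  q <- numeric(n_components)
  Xd <- X
  yd <- y
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      abort("no covariance left between X and y; reduce n_components",
            class = "nmrmet_fit_error")
    }
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    pp <- drop(crossprod(Xd, tt)) / tt2
    qq <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pp)
    yd <- yd - tt * qq
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; q[a] <- qq
  }
  # regression vector on the scaled X space
  b <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, T = Tm, q = q, b = drop(b), X_res = Xd)
}

#' Partial least squares discriminant analysis (two classes)
#'
#' NIPALS PLS1 against the 0/1 class membership: each component maximizes the
#' covariance between the scaled spectra and the class vector, with X and y
#' deflation between components. Reports `r2x`, `r2y` and (optionally) the
#' stratified 7-fold cross-validated `q2`.
#'
#' @param x An `nmr_binned` object, matrix or data frame.
#' @param group Two-level class labels (taken from `x` when it is an
#'   `nmr_binned`).
#' @param n_components Number of predictive components.
#' @param scaling Column scaling, as in [fit_pca()].
#' @param cv Compute cross-validated `q2` (default `TRUE`).
#' @param cv_folds,cv_seed Folds and seed for [cross_validate()].
#' @return An `nmr_latent` model (`kind = "plsda"`).
#' @export
fit_plsda <- function(x, group = NULL, n_components = 2, scaling = "uv",
                      cv = TRUE, cv_folds = 7, cv_seed = 1) {
  rx <- resolve_x(x, group)
  enc <- encode_y(rx$group)
  sc <- scale_columns(rx$X, scaling)
  yc <- enc$y - mean(enc$y)
  fit <- pls1_core(sc$X, yc, n_components)
  ssy <- sum(yc^2)
  yhat <- drop(sc$X %*% fit$b)
  r2y <- 1 - sum((yc - yhat)^2) / ssy
  r2x <- 1 - sum(fit$X_res^2) / sum(sc$X^2)
  q2 <- if (cv) {
    cross_validate(x, rx$group, method = "plsda", n_components = n_components,
                   k = cv_folds, seed = cv_seed, scaling = scaling)
  } else {
    NA_real_
  }
  scores <- fit$T
  dimnames(scores) <- list(rx$sample_id, paste0("t", seq_len(n_components)))
  dimnames(fit$P) <- dimnames(fit$W) <-
    list(colnames(rx$X), paste0("t", seq_len(n_components)))
  new_latent(
    kind = "plsda", scores = scores, loadings = fit$P, weights = fit$W,
    q_loadings = fit$q, b = fit$b, r2x = r2x, r2y = r2y, q2 = q2,
    n_components = n_components, n_orth = 0L, scaling = sc$scaling,
    center = sc$center, scale = sc$scale, y_mean = mean(enc$y),
    sample_id = rx$sample_id, group = enc$group, y = enc$y,
    levels = enc$levels, variable_ppm = rx$variable_ppm, X = rx$X
  )
}

#' Orthogonal PLS discriminant analysis (two classes)
#'
#' Removes `n_orth` components of X-variation orthogonal to the class vector
#' (orthogonal signal correction), then fits a single predictive component
#' carrying the class contrast (tp1). With `n_orth = 0` the model reduces
#' exactly to one-component PLS-DA. Orthogonal scores have zero covariance
#' with y by construction.
#'
#' @inheritParams fit_plsda
#' @param n_orth Number of orthogonal components removed (default 1).
#' @return An `nmr_latent` model (`kind = "oplsda"`) with predictive
#'   `scores` (tp1), `orth_scores` and `orth_loadings`.
#' @export
fit_oplsda <- function(x, group = NULL, n_orth = 1, scaling = "uv",
                       cv = TRUE, cv_folds = 7, cv_seed = 1) {
  if (n_orth < 0) abort("n_orth must be >= 0", class = "nmrmet_fit_error")
  rx <- resolve_x(x, group)
  enc <- encode_y(rx$group)
  sc <- scale_columns(rx$X, scaling)
  yc <- enc$y - mean(enc$y)
  ofit <- opls_core(sc$X, yc, n_orth)
  ssy <- sum(yc^2)
  yhat <- ofit$t * ofit$q
  r2y <- 1 - sum((yc - yhat)^2) / ssy
  X_res <- ofit$Xp - tcrossprod(ofit$t, ofit$p)
  r2x <- 1 - sum(X_res^2) / sum(sc$X^2)
  q2 <- if (cv) {
    cross_validate(x, rx$group, method = "oplsda", n_orth = n_orth,
                   k = cv_folds, seed = cv_seed, scaling = scaling)
  } else {
    NA_real_
  }
  scores <- matrix(ofit$t, ncol = 1, dimnames = list(rx$sample_id, "tp1"))
  vn <- colnames(rx$X)
  new_latent(
    kind = "oplsda",
    scores = scores,
    loadings = matrix(ofit$p, ncol = 1, dimnames = list(vn, "tp1")),
    weights = matrix(ofit$w, ncol = 1, dimnames = list(vn, "tp1")),
    q_loadings = ofit$q,
    orth_scores = ofit$T_orth, orth_loadings = ofit$P_orth,
    orth_weights = ofit$W_orth,
    r2x = r2x, r2y = r2y, q2 = q2, n_components = 1L,
    n_orth = as.integer(n_orth), scaling = sc$scaling,
    center = sc$center, scale = sc$scale, y_mean = mean(enc$y),
    sample_id = rx$sample_id, group = enc$group, y = enc$y,
    levels = enc$levels, variable_ppm = rx$variable_ppm, X = rx$X
  )
}

# O-PLS (Trygg & Wold): strip y-orthogonal structure, then one predictive
# component on the filtered matrix
opls_core <- function(X, yc, n_orth) {
  p <- ncol(X)
  W_orth <- matrix(0, p, max(n_orth, 0))
  P_orth <- matrix(0, p, max(n_orth, 0))
  T_orth <- matrix(0, nrow(X), max(n_orth, 0))
  Xd <- X
  for (a in seq_len(n_orth)) {
    w <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) abort("degenerate X'y", class = "nmrmet_fit_error")
    w <- w / nw
    tt <- drop(Xd %*% w)
    pp <- drop(crossprod(Xd, tt)) / sum(tt^2)
    wo <- pp - drop(crossprod(w, pp)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break # no orthogonal structure left
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    W_orth[, a] <- wo; P_orth[, a] <- po; T_orth[, a] <- to
  }
  w <- drop(crossprod(Xd, yc))
  w <- w / sqrt(sum(w^2))
  tt <- drop(Xd %*% w)
  tt2 <- sum(tt^2)
  pp <- drop(crossprod(Xd, tt)) / tt2
  qq <- sum(yc * tt) / tt2
  list(w = w, t = tt, p = pp, q = qq,
       W_orth = W_orth, P_orth = P_orth, T_orth = T_orth, Xp = Xd)
}

# predict centred-y values for new raw data
predict_latent <- function(model, newX) {
  Xs <- sweep(sweep(newX, 2, model$center), 2, model$scale, "/")
  if (model$kind == "oplsda") {
    for (a in seq_len(model$n_orth)) {
      to <- drop(Xs %*% model$orth_weights[, a])
      Xs <- Xs - tcrossprod(to, model$orth_loadings[, a])
    }
    drop(Xs %*% model$weights[, 1]) * model$q_loadings + model$y_mean
  } else if (model$kind == "plsda") {
    drop(Xs %*% model$b) + model$y_mean
  } else {
    abort("prediction requires a plsda or oplsda model",
          class = "nmrmet_type_error")
  }
}

stratified_folds <- function(group, k, seed) {
  g <- droplevels(factor(group))
  if (k < 2) abort("k must be >= 2", class = "nmrmet_fold_error")
  if (k > min(table(g))) {
    abort("k exceeds the smallest class size", class = "nmrmet_fold_error")
  }
  folds <- integer(length(g))
  with_seed_(seed, {
    for (lv in levels(g)) {
      idx <- sample(which(g == lv))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated predictive ability (Q2)
#'
#' Stratified k-fold cross-validation of a PLS-DA or OPLS-DA model:
#' `Q2 = 1 - PRESS / SS`, with `SS` the total corrected sum of squares of the
#' encoded class vector and `PRESS` the pooled squared prediction error over
#' held-out folds. Folds are stratified by class and fixed by `seed`.
#'
#' @param x An `nmr_binned` object, matrix or data frame.
#' @param group Two-level class labels.
#' @param method `"oplsda"` (default) or `"plsda"`.
#' @param n_components Predictive components (plsda).
#' @param n_orth Orthogonal components (oplsda).
#' @param k Number of folds (default 7, the SIMCA convention).
#' @param seed Fold-assignment seed.
#' @param scaling Column scaling.
#' @return The `q2` fraction (scalar, attributes `press` and `ss`).
#' @export
cross_validate <- function(x, group = NULL, method = c("oplsda", "plsda"),
                           n_components = 1, n_orth = 1, k = 7, seed = 1,
                           scaling = "uv") {
  method <- match.arg(method)
  rx <- resolve_x(x, group)
  enc <- encode_y(rx$group)
  folds <- stratified_folds(enc$group, k, seed)
  press <- 0
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- if (method == "plsda") {
      fit_plsda(rx$X[tr, , drop = FALSE], enc$group[tr],
                n_components = n_components, scaling = scaling, cv = FALSE)
    } else {
      fit_oplsda(rx$X[tr, , drop = FALSE], enc$group[tr], n_orth = n_orth,
                 scaling = scaling, cv = FALSE)
    }
    pred <- predict_latent(fit, rx$X[!tr, , drop = FALSE])
    press <- press + sum((enc$y[!tr] - pred)^2)
  }
  ss <- sum((enc$y - mean(enc$y))^2)
  structure(1 - press / ss, press = press, ss = ss)
}

#' Response permutation testing (RPT)
#'
#' Refits the model `n_perm` times under randomly permuted class labels,
#' keeping the unpermuted model's component structure, and reports for each
#' permutation the absolute correlation of the permuted class vector with
#' the original, plus the refitted `R2Y` and `Q2`. Regression intercepts of
#' `R2Y` and `Q2` against the correlation (the observed model included at
#' correlation 1) summarize overfitting; the empirical p-value is
#' `(1 + #\{q2_perm >= q2_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams cross_validate
#' @param n_perm Number of permutations (>= 20; default 200).
#' @param seed Permutation seed (also fixes CV folds).
#' @return An `nmr_permutation` object: `permutations` tibble
#'   (`correlation`, `r2y`, `q2`, `observed`), `rpt_intercepts`, and
#'   `empirical_p`.
#' @export
permutation_test <- function(x, group = NULL, method = c("oplsda", "plsda"),
                             n_perm = 200, seed = 1, n_components = 1,
                             n_orth = 1, k = 7, scaling = "uv") {
  method <- match.arg(method)
  if (n_perm < 20) abort("n_perm must be >= 20", class = "nmrmet_config_error")
  rx <- resolve_x(x, group)
  enc <- encode_y(rx$group)
  fit_once <- function(g, cv_seed) {
    m <- if (method == "plsda") {
      fit_plsda(rx$X, g, n_components = n_components, scaling = scaling,
                cv = FALSE)
    } else {
      fit_oplsda(rx$X, g, n_orth = n_orth, scaling = scaling, cv = FALSE)
    }
    q2 <- cross_validate(rx$X, g, method = method,
                         n_components = n_components, n_orth = n_orth,
                         k = k, seed = cv_seed, scaling = scaling)
    c(r2y = m$r2y, q2 = as.numeric(q2))
  }
  obs <- fit_once(enc$group, cv_seed = seed)
  perm <- with_seed_(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      gp <- sample(enc$group)
      yp <- as.numeric(gp == levels(enc$group)[2])
      c(correlation = abs(cor(yp, enc$y)), fit_once(gp, cv_seed = seed))
    }, c(correlation = 0, r2y = 0, q2 = 0)))
  })
  tab <- dplyr::bind_rows(
    tibble::as_tibble(perm) |> dplyr::mutate(observed = FALSE),
    tibble::tibble(correlation = 1, r2y = obs[["r2y"]], q2 = obs[["q2"]],
                   observed = TRUE)
  )
  r2_int <- unname(stats::coef(stats::lm(r2y ~ correlation, data = tab))[1])
  q2_int <- unname(stats::coef(stats::lm(q2 ~ correlation, data = tab))[1])
  structure(
    list(
      permutations = tab,
      rpt_intercepts = c(r2_intercept = r2_int, q2_intercept = q2_int),
      empirical_p = (1 + sum(perm[, "q2"] >= obs[["q2"]])) / (n_perm + 1),
      observed = c(r2y = obs[["r2y"]], q2 = obs[["q2"]]),
      n_perm = n_perm, method = method
    ),
    class = "nmr_permutation"
  )
}

#' @export
print.nmr_permutation <- function(x, ...) {
  cat("<nmr_permutation> ", x$n_perm, " permutations (", x$method, ")\n",
      "  observed R2Y = ", round(x$observed["r2y"], 3),
      ", Q2 = ", round(x$observed["q2"], 3), "\n",
      "  intercepts: R2Y = ", round(x$rpt_intercepts["r2_intercept"], 3),
      ", Q2 = ", round(x$rpt_intercepts["q2_intercept"], 3), "\n",
      "  empirical p = ", signif(x$empirical_p, 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy nmr_permutation
#' @export
tidy.nmr_permutation <- function(x, ...) x$permutations

#' @method glance nmr_permutation
#' @export
glance.nmr_permutation <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm,
    r2y = unname(x$observed["r2y"]),
    q2 = unname(x$observed["q2"]),
    r2_intercept = unname(x$rpt_intercepts["r2_intercept"]),
    q2_intercept = unname(x$rpt_intercepts["q2_intercept"]),
    empirical_p = x$empirical_p
  )
}

#' CV-ANOVA significance test for a latent-variable model
#'
#' F-test comparing the cross-validated predictive residuals (PRESS) with the
#' total corrected variation of the class vector, following the Eriksson
#' construction: `SS_reg = SS - PRESS` on `A` degrees of freedom (the total
#' number of fitted components) against `PRESS` on `n - A - 1`. A model whose
#' cross-validated predictions do no better than the class mean
#' (`PRESS >= SS`) is reported with `F = 0`, `p = 1`.
#'
#' @inheritParams cross_validate
#' @return A one-row tibble: `F`, `df1`, `df2`, `p`.
#' @export
cv_anova <- function(x, group = NULL, method = c("oplsda", "plsda"),
                     n_components = 1, n_orth = 1, k = 7, seed = 1,
                     scaling = "uv") {
  method <- match.arg(method)
  q2 <- cross_validate(x, group, method = method, n_components = n_components,
                       n_orth = n_orth, k = k, seed = seed, scaling = scaling)
  press <- attr(q2, "press")
  ss <- attr(q2, "ss")
  n <- if (inherits(x, "nmr_binned")) nrow(x$values) else nrow(as.matrix(x))
  A <- if (method == "oplsda") 1L + as.integer(n_orth) else
    as.integer(n_components)
  df1 <- A
  df2 <- n - A - 1L
  if (df2 < 1) abort("too few samples for CV-ANOVA", class = "nmrmet_fit_error")
  Fv <- max(0, ((ss - press) / df1) / (press / df2))
  p <- if (press >= ss) 1 else pf(Fv, df1, df2, lower.tail = FALSE)
  tibble::tibble(F = Fv, df1 = df1, df2 = df2, p = p)
}

#' Variable importance in the projection (VIP)
#'
#' Weight-based importance over the predictive component(s):
#' `VIP_j = sqrt(p * sum_a(w_aj^2 SSY_a) / sum_a(SSY_a))`, where `SSY_a` is
#' the y-variation explained by component `a`. Squared VIPs average to one
#' over the active variables; `VIP > 1` flags influential variables.
#'
#' @param model A fitted `nmr_latent` of kind `plsda` or `oplsda`.
#' @return A tibble `variable`, `ppm` (if available), `vip`.
#' @export
vip <- function(model) {
  if (!inherits(model, "nmr_latent") || model$kind == "pca") {
    abort("VIP requires a plsda or oplsda model", class = "nmrmet_type_error")
  }
  W <- model$weights
  Tm <- model$scores
  q <- model$q_loadings
  ssy <- vapply(seq_len(ncol(Tm)),
                function(a) sum(Tm[, a]^2) * q[a]^2, numeric(1))
  p <- nrow(W)
  v <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  tibble::tibble(
    variable = rownames(W),
    ppm = if (is.null(model$variable_ppm)) NA_real_ else model$variable_ppm,
    vip = unname(v)
  )
}

#' Correlation loadings against the predictive score
#'
#' Pearson correlation of each variable with the predictive score tp1.
#' Zero-variance variables are undefined and reported as 0 with
#' `zero_variance = TRUE`.
#'
#' @param model A fitted `nmr_latent` with predictive scores.
#' @return A tibble `variable`, `ppm` (if available), `r`, `zero_variance`.
#' @export
correlation_loadings <- function(model) {
  if (!inherits(model, "nmr_latent") || model$kind == "pca") {
    abort("correlation loadings require a plsda or oplsda model",
          class = "nmrmet_type_error")
  }
  tp1 <- model$scores[, 1]
  mu <- colMeans(model$X)
  sds <- sqrt(colSums((model$X - rep(mu, each = nrow(model$X)))^2) /
                max(nrow(model$X) - 1, 1))
  r <- rep(0, ncol(model$X))
  ok <- sds > 0
  r[ok] <- drop(cor(model$X[, ok, drop = FALSE], tp1))
  tibble::tibble(
    variable = colnames(model$X),
    ppm = if (is.null(model$variable_ppm)) NA_real_ else model$variable_ppm,
    r = r,
    zero_variance = !ok
  )
}

#' @export
print.nmr_latent <- function(x, ...) {
  cat("<nmr_latent> ", toupper(x$kind), ": ", x$n_components,
      " predictive component(s)",
      if (x$n_orth > 0) paste0(" + ", x$n_orth, " orthogonal"), "\n",
      "  R2X = ", round(x$r2x, 3),
      if (!is.na(x$r2y)) paste0(", R2Y = ", round(x$r2y, 3)),
      if (!is.na(x$q2)) paste0(", Q2 = ", round(x$q2, 3)), "\n", sep = "")
  invisible(x)
}

#' Scores of a latent model in long form
#'
#' @param x An `nmr_latent` model.
#' @param ... Unused.
#' @return Tibble `sample_id`, `group`, `component`, `score`.
#' @method tidy nmr_latent
#' @export
tidy.nmr_latent <- function(x, ...) {
  sc <- x$scores
  tibble::tibble(
    sample_id = rep(rownames(sc), times = ncol(sc)),
    group = if (is.null(x$group)) NA else rep(x$group, times = ncol(sc)),
    component = rep(colnames(sc), each = nrow(sc)),
    score = as.vector(sc)
  )
}

#' One-row model summary
#'
#' @param x An `nmr_latent` model.
#' @param ... Unused.
#' @return Tibble `kind`, `n_components`, `n_orth`, `r2x`, `r2y`, `q2`,
#'   `scaling`.
#' @method glance nmr_latent
#' @export
glance.nmr_latent <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_components = x$n_components,
                 n_orth = x$n_orth, r2x = x$r2x, r2y = x$r2y,
                 q2 = as.numeric(x$q2), scaling = x$scaling)
}
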