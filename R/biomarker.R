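#' Receiver operating characteristic curve from a per-sample score
#'
#' Sweeps thresholds over the unique score values, computes sensitivity and
#' specificity at each, and reports the trapezoidal AUC and the cutoff at the
#' maximum Youden index (sensitivity + specificity - 1). When `orient` is
#' `TRUE` (default) the score polarity is chosen so that AUC >= 0.5 and the
#' chosen polarity is recorded.
#'
#' @param scores Per-sample numeric values.
#' @param labels Binary class labels (factor, character or 0/1).
#' @param positive The positive-class label; defaults to the second level in
#'   sorted order.
#' @param orient Normalize polarity so AUC >= 0.5.
#' @return An `nmr_roc` object: `points` tibble (`threshold`, `fpr`, `tpr`),
#'   `auc`, `cutoff`, `youden`, `polarity`, counts.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c("a", "a", "b", "b"))$auc # 1
#' @export
roc_curve <- function(scores, labels, positive = NULL, orient = TRUE) {
  lab <- factor(labels)
  if (nlevels(droplevels(lab)) != 2) {
    abort("labels must contain exactly two classes", class = "nmrmet_roc_error")
  }
  lab <- droplevels(lab)
  positive <- positive %||% levels(lab)[2]
  if (!positive %in% levels(lab)) {
    abort("positive class not present in labels", class = "nmrmet_roc_error")
  }
  pos <- lab == positive
  polarity <- 1
  a <- auc_raw(scores, pos)
  if (orient && a < 0.5) {
    polarity <- -1
    scores <- -scores
  }
  pts <- roc_points(scores, pos)
  auc <- trapezoid_auc(pts$fpr, pts$tpr)
  yi <- pts$tpr - pts$fpr
  best <- which.max(yi)
  structure(
    list(points = pts, auc = auc,
         cutoff = polarity * pts$threshold[best],
         youden = yi[best], polarity = polarity, positive = positive,
         n_pos = sum(pos), n_neg = sum(!pos),
         per_sample = tibble::tibble(score = polarity * scores,
                                     label = lab, positive = pos)),
    class = "nmr_roc"
  )
}

# points swept over unique scores; predict positive when score >= threshold
roc_points <- function(scores, pos) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(tt) mean(scores[pos] >= tt), numeric(1))
  fpr <- vapply(thr, function(tt) mean(scores[!pos] >= tt), numeric(1))
  tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
}

# raw (unoriented) trapezoidal AUC
auc_raw <- function(scores, pos) {
  pts <- roc_points(scores, pos)
  trapezoid_auc(pts$fpr, pts$tpr)
}

#' @export
print.nmr_roc <- function(x, ...) {
  cat("<nmr_roc> AUC = ", round(x$auc, 3), " (", x$n_pos, " positive / ",
      x$n_neg, " negative; positive class '", x$positive, "')\n",
      "  Youden cutoff = ", signif(x$cutoff, 4),
      if (x$polarity < 0) " (inverted polarity)", "\n", sep = "")
  invisible(x)
}

#' @method tidy nmr_roc
#' @export
tidy.nmr_roc <- function(x, ...) x$points

#' @method glance nmr_roc
#' @export
glance.nmr_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutoff = x$cutoff, youden = x$youden,
                 polarity = x$polarity, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Metabolite-ratio diagnostic feature
#'
#' Elementwise ratio of two quantified metabolites (e.g. acetate/glycerol or
#' lactate/citrate), used as a single discriminative mark.
#'
#' @param quant Metabolite table from [quantify_metabolites()].
#' @param numerator,denominator Metabolite column names.
#' @return Tibble `sample_id`, `group`, `ratio`.
#' @export
ratio_feature <- function(quant, numerator, denominator) {
  for (m in c(numerator, denominator)) {
    if (!m %in% names(quant)) {
      abort(paste0("metabolite '", m, "' not present in the table"),
            class = "nmrmet_config_error")
    }
  }
  den <- quant[[denominator]]
  bad <- which(!(den > 0))
  if (length(bad)) {
    abort(paste0("non-positive denominator '", denominator,
                 "' for sample(s): ",
                 paste(quant$sample_id[bad], collapse = ", ")),
          class = "nmrmet_domain_error")
  }
  tibble::tibble(sample_id = quant$sample_id, group = quant$group,
                 ratio = quant[[numerator]] / den)
}

#' Monte-Carlo multivariate ROC analysis with random-forest feature ranking
#'
#' Repeated stratified splits (two thirds training, one third test). Within
#' each split, features are ranked by random-forest importance on the
#' training data, the top `n_features` are kept, a random-forest classifier
#' is fitted on them, and class probabilities are collected for the held-out
#' samples. Per-sample predicted probabilities are averaged over the splits
#' in which the sample was held out, and a single pooled ROC/AUC is computed
#' from the averaged probabilities. The feature ranking reports how often
#' each feature entered a split's top set.
#'
#' @param quant Metabolite table (`sample_id`, `group`, features) restricted
#'   to two groups.
#' @param n_features Features retained per split (default 5).
#' @param n_splits Number of Monte-Carlo splits (>= 10; default 100).
#' @param seed RNG seed.
#' @param n_trees Trees per forest (default 500).
#' @param positive Positive class (default second sorted level).
#' @return An `nmr_mroc` object: `roc` (`nmr_roc` over averaged
#'   probabilities), `ranking` tibble (`feature`, `frequency`, ties broken
#'   alphabetically), `probabilities` tibble (`sample_id`, `group`,
#'   `probability`, `n_tested`).
#' @export
multivariate_roc <- function(quant, n_features = 5, n_splits = 100, seed = 1,
                             n_trees = 500, positive = NULL) {
  if (n_splits < 10) {
    abort("n_splits must be >= 10 for stable estimates",
          class = "nmrmet_config_error")
  }
  g <- droplevels(factor(quant$group))
  if (nlevels(g) != 2) {
    abort("quant must contain exactly two groups", class = "nmrmet_roc_error")
  }
  features <- setdiff(names(quant), c("sample_id", "group"))
  if (length(features) < n_features) {
    abort("fewer features than n_features", class = "nmrmet_config_error")
  }
  X <- as.data.frame(quant[, features, drop = FALSE])
  names(X) <- make.names(names(X))
  feat_key <- setNames(features, make.names(features))
  positive <- positive %||% levels(g)[2]
  n <- nrow(X)
  prob_sum <- numeric(n)
  prob_n <- integer(n)
  sel <- setNames(integer(length(features)), features)
  with_seed_(seed, {
    for (s in seq_len(n_splits)) {
      tr <- logical(n)
      for (lv in levels(g)) {
        idx <- which(g == lv)
        tr[sample(idx, ceiling(2 * length(idx) / 3))] <- TRUE
      }
      rf_rank <- randomForest::randomForest(
        x = X[tr, , drop = FALSE], y = g[tr], ntree = n_trees)
      imp <- randomForest::importance(rf_rank)[, 1]
      ord <- order(-imp, names(imp)) # ties broken alphabetically
      top <- names(imp)[ord][seq_len(n_features)]
      sel[feat_key[top]] <- sel[feat_key[top]] + 1L
      rf <- randomForest::randomForest(
        x = X[tr, top, drop = FALSE], y = g[tr], ntree = n_trees)
      pr <- predict(rf, X[!tr, top, drop = FALSE], type = "prob")[, positive]
      prob_sum[!tr] <- prob_sum[!tr] + pr
      prob_n[!tr] <- prob_n[!tr] + 1L
    }
  })
  tested <- prob_n > 0
  probs <- tibble::tibble(
    sample_id = quant$sample_id[tested],
    group = g[tested],
    probability = prob_sum[tested] / prob_n[tested],
    n_tested = prob_n[tested]
  )
  roc <- roc_curve(probs$probability, probs$group, positive = positive,
                   orient = FALSE)
  roc$per_sample_prob <- probs
  ranking <- tibble::tibble(feature = names(sel),
                            frequency = unname(sel) / n_splits) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$feature)
  structure(list(roc = roc, ranking = ranking, probabilities = probs,
                 n_features = n_features, n_splits = n_splits,
                 positive = positive),
            class = "nmr_mroc")
}

#' @export
print.nmr_mroc <- function(x, ...) {
  cat("<nmr_mroc> pooled AUC = ", round(x$roc$auc, 3), " (",
      x$n_features, " features, ", x$n_splits, " splits)\n", sep = "")
  print(head(x$ranking, x$n_features))
  invisible(x)
}

#' @method glance nmr_mroc
#' @export
glance.nmr_mroc <- function(x, ...) {
  tibble::tibble(auc = x$roc$auc, n_features = x$n_features,
                 n_splits = x$n_splits, positive = x$positive)
}

#' @method tidy nmr_mroc
#' @export
tidy.nmr_mroc <- function(x, ...) x$ranking

#' Validate a diagnostic feature set with a linear SVM on held-out samples
#'
#' Fits a linear-kernel support vector machine on the training table and
#' reports accuracy, sensitivity and specificity on a disjoint validation
#' table. Overlapping sample ids between the two tables raise a leakage
#' error.
#'
#' @param train,test Tibbles with `sample_id`, `group` and identical feature
#'   columns; sample ids must be disjoint.
#' @param positive Positive class for sensitivity/specificity (default
#'   second sorted level).
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `n_train`, `n_test`, `positive`.
#' @export
svm_validate <- function(train, test, positive = NULL) {
  overlap <- intersect(train$sample_id, test$sample_id)
  if (length(overlap)) {
    abort(paste0("train/test sample ids overlap (leakage): ",
                 paste(head(overlap, 5), collapse = ", ")),
          class = "nmrmet_leakage_error")
  }
  features <- setdiff(names(train), c("sample_id", "group"))
  if (!all(features %in% names(test))) {
    abort("train and test must share feature columns",
          class = "nmrmet_config_error")
  }
  gtr <- droplevels(factor(train$group))
  gte <- factor(test$group, levels = levels(gtr))
  if (nlevels(gtr) != 2 || anyNA(gte)) {
    abort("two classes required and test labels must match training levels",
          class = "nmrmet_config_error")
  }
  positive <- positive %||% levels(gtr)[2]
  fit <- e1071::svm(x = as.matrix(train[, features, drop = FALSE]), y = gtr,
                    kernel = "linear")
  pred <- predict(fit, as.matrix(test[, features, drop = FALSE]))
  acc <- mean(pred == gte)
  pos <- gte == positive
  tibble::tibble(
    accuracy = acc,
    sensitivity = if (any(pos)) mean(pred[pos] == positive) else NA_real_,
    specificity = if (any(!pos)) mean(pred[!pos] != positive) else NA_real_,
    n_train = nrow(train), n_test = nrow(test), positive = positive
  )
}
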