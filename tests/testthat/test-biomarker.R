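test_that("ROC handles separation, null scores and orientation", {
  r <- roc_curve(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_true(r$cutoff > 3 && r$cutoff <= 10)

  set.seed(51)
  scores <- rnorm(2000)
  labs <- sample(rep(c("a", "b"), 1000))
  rn <- roc_curve(scores, labs, orient = FALSE)
  expect_lt(abs(rn$auc - 0.5), 0.03)

  # anti-correlated score is flipped so AUC >= 0.5, polarity recorded
  ra <- roc_curve(-c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(ra$auc, 1)
  expect_equal(ra$polarity, -1)

  expect_error(roc_curve(1:5, rep("a", 5)), class = "nmrmet_roc_error")
})

test_that("trapezoid AUC equals the concordant-pair count oracle", {
  set.seed(52)
  for (i in 1:20) {
    scores <- sample(1:8, 30, replace = TRUE) # heavy ties
    pos <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (length(unique(pos)) < 2) next
    r <- roc_curve(scores, factor(ifelse(pos, "p", "n")), positive = "p",
                   orient = FALSE)
    expect_equal(r$auc, pair_count_auc(scores, pos), tolerance = 1e-12)
    # trapezoid area of the reported points reproduces auc exactly
    pts <- r$points
    expect_equal(sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2),
                 r$auc, tolerance = 1e-12)
  }
})

test_that("AUC of flipped labels complements the raw AUC exactly", {
  set.seed(53)
  scores <- c(rnorm(20), rnorm(15, 1))
  labs <- rep(c("n", "p"), c(20, 15))
  a1 <- roc_curve(scores, labs, positive = "p", orient = FALSE)$auc
  a2 <- roc_curve(scores, labs, positive = "n", orient = FALSE)$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  scores <- rnorm(60)
  labs <- rep(c("n", "p"), 30)
  scores[labs == "p"] <- scores[labs == "p"] + 0.8
  ours <- roc_curve(scores, labs, positive = "p", orient = FALSE)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labs, scores, levels = c("n", "p"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the reported cutoff maximizes the Youden index", {
  set.seed(55)
  scores <- round(rnorm(40), 1)
  labs <- rep(c("n", "p"), 20)
  scores[labs == "p"] <- scores[labs == "p"] + 1
  r <- roc_curve(scores, labs, positive = "p")
  youden_at <- function(cut) {
    mean(scores[labs == "p"] >= cut) - mean(scores[labs == "n"] >= cut)
  }
  best <- max(vapply(sort(unique(scores)), youden_at, numeric(1)))
  expect_equal(r$youden, best, tolerance = 1e-12)
  expect_equal(youden_at(r$cutoff), best, tolerance = 1e-12)
})

test_that("ratio features are elementwise and guard their domain", {
  quant <- tibble::tibble(sample_id = paste0("s", 1:4),
                          group = factor(rep(c("a", "b"), 2)),
                          Acetate = c(1, 2, 3, 4), Glycerol = c(1, 2, 3, 4),
                          Citrate = c(2, 2, 2, 2))
  expect_equal(ratio_feature(quant, "Acetate", "Glycerol")$ratio, rep(1, 4))
  doubled <- dplyr::mutate(quant, Acetate = Acetate * 2)
  expect_equal(ratio_feature(doubled, "Acetate", "Glycerol")$ratio,
               2 * ratio_feature(quant, "Acetate", "Glycerol")$ratio)
  bad <- dplyr::mutate(quant, Citrate = c(1, 0, 1, -1))
  expect_error(ratio_feature(bad, "Acetate", "Citrate"), "s2",
               class = "nmrmet_domain_error")
  expect_error(ratio_feature(quant, "Acetate", "Missing"),
               class = "nmrmet_config_error")
})

test_that("multivariate ROC finds planted biomarkers and is deterministic", {
  set.seed(56)
  n <- 40
  g <- rep(c("case", "control"), each = n / 2)
  X <- matrix(rlnorm(n * 10, 0, 0.3), n)
  colnames(X) <- c(paste0("null", 1:8), "bioA", "bioB")
  X[g == "case", 9] <- X[g == "case", 9] * 2.5
  X[g == "case", 10] <- X[g == "case", 10] * 0.4
  quant <- dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", 1:n), group = g),
    tibble::as_tibble(X))
  mr <- multivariate_roc(quant, n_features = 3, n_splits = 50, seed = 8,
                         positive = "case")
  freq <- setNames(mr$ranking$frequency, mr$ranking$feature)
  expect_gt(freq[["bioA"]], 0.9)
  expect_gt(freq[["bioB"]], 0.9)
  expect_gt(mr$roc$auc, 0.9)
  mr2 <- multivariate_roc(quant, n_features = 3, n_splits = 50, seed = 8,
                          positive = "case")
  expect_identical(mr$roc$auc, mr2$roc$auc)
  expect_identical(mr$ranking, mr2$ranking)
  # saturation: keeping every feature selects each in every split
  mrs <- multivariate_roc(quant, n_features = 10, n_splits = 10, seed = 8)
  expect_true(all(mrs$ranking$frequency == 1))
  expect_error(multivariate_roc(quant, n_splits = 5),
               class = "nmrmet_config_error")
  expect_error(multivariate_roc(quant, n_features = 99),
               class = "nmrmet_config_error")
})

test_that("SVM validation scores held-out ratios and catches leakage", {
  set.seed(57)
  mk <- function(ids, sep) {
    n <- length(ids)
    g <- rep(c("case", "control"), length.out = n)
    tibble::tibble(sample_id = ids, group = g,
                   ratio = rnorm(n, ifelse(g == "case", sep, 0), 0.1))
  }
  train <- mk(paste0("tr", 1:40), sep = 5)
  test <- mk(paste0("te", 1:40), sep = 5)
  res <- svm_validate(train, test)
  expect_equal(res$accuracy, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)

  # shuffled labels: accuracy near the class prior
  trn <- mk(paste0("tr", 1:60), sep = 0)
  ten <- mk(paste0("te", 1:60), sep = 0)
  resn <- svm_validate(trn, ten)
  expect_gt(resn$accuracy, 0.25)
  expect_lt(resn$accuracy, 0.75)

  expect_error(svm_validate(train, train), class = "nmrmet_leakage_error")
})
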