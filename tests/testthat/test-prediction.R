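# Outcome prediction: stratified splitting, SVM fitness, GA selection,
# holdout evaluation, shuffle inference, elastic net and bootstrap.

test_that("stratified split reproduces the 91 -> 64/27 partition", {
  tb <- fixture_feature_table(n = 91, seed = 2)
  tb$asd_outcome <- rep(c(FALSE, TRUE), c(72, 19))
  sp <- stratified_split(tb, 0.7, seed = 4)
  expect_equal(nrow(sp$train), 64)
  expect_equal(nrow(sp$holdout), 27)
  expect_true(sum(sp$train$asd_outcome) %in% 13:14)
  expect_true(sum(sp$holdout$asd_outcome) %in% 5:6)
  # disjoint and exhaustive
  expect_setequal(c(sp$train$subject_id, sp$holdout$subject_id),
                  tb$subject_id)
  # deterministic under the same seed
  sp2 <- stratified_split(tb, 0.7, seed = 4)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  # degenerate fractions and classes rejected
  expect_error(stratified_split(tb, 1.0, seed = 1), "strictly between")
  tb1 <- tb; tb1$asd_outcome <- TRUE
  expect_error(stratified_split(tb1, 0.7), "both outcome classes")
})

test_that("rank-based AUC agrees with pROC and the SVM fitness behaves", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- runif(60) > 0.6
  s <- rnorm(60) + 0.8 * y
  expect_equal(erpstates:::auc_wmw(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)

  # a perfectly separating feature gives AUC 1
  tb <- fixture_feature_table(n = 40, p = 4, seed = 6)
  tb$f1 <- ifelse(tb$asd_outcome, 5 + runif(40), -5 - runif(40))
  expect_equal(svm_cv_auc(tb, "f1", folds = 10, seed = 1), 1)

  # permuted labels at larger n give chance-level AUC
  tb2 <- fixture_feature_table(n = 200, p = 6, seed = 7)
  set.seed(8)
  tb2$asd_outcome <- sample(tb2$asd_outcome)
  a <- svm_cv_auc(tb2, paste0("f", 1:6), folds = 10, seed = 2)
  expect_lt(abs(a - 0.5), 0.1)
  expect_error(svm_cv_auc(tb2, character(0)), "at least one feature")
})

test_that("GA selection is reproducible and respects a single feature", {
  tb <- fixture_feature_table(n = 40, p = 2, seed = 9, separation = 2)
  p1 <- ga_params(population_size = 8, n_generations = 5, n_evolutions = 2,
                  seed = 11)
  s1 <- suppressWarnings(ga_select(tb, p1, features = c("f1", "f2")))
  s2 <- suppressWarnings(ga_select(tb, p1, features = c("f1", "f2")))
  expect_identical(s1$incidence, s2$incidence)
  expect_identical(s1$optimal_set, s2$optimal_set)
  expect_true(all(s1$evolutions$best_auc >= 0.5))
  expect_error(ga_select(tb, p1, features = "f1"), "at least 2")
})

test_that("confusion metrics match their closed forms incl. the worked case", {
  m <- confusion_metrics(tp = 2, fn = 3, tn = 5, fp = 0)
  expect_equal(unname(m["sensitivity"]), 40)
  expect_equal(unname(m["specificity"]), 100)
  expect_equal(unname(m["ppv"]), 100)
  expect_equal(unname(m["npv"]), 62.5)
  expect_equal(unname(m["accuracy"]), 70)
  # zero denominators are missing, not zero
  expect_true(is.na(confusion_metrics(0, 0, 5, 2)["sensitivity"]))
  expect_true(is.na(confusion_metrics(0, 3, 5, 0)["ppv"]))
})

test_that("holdout evaluation reports consistent metrics and confusions", {
  tb <- fixture_feature_table(n = 80, p = 4, seed = 12, separation = 3)
  sp <- stratified_split(tb, 0.7, seed = 1)
  rep <- evaluate_classifier(sp$train, sp$holdout, c("f1", "f2"),
                             n_repetitions = 30, seed = 2)
  expect_s3_class(rep, "classifier_report")
  # metric identities: recompute every repetition from stored confusions
  for (r in seq_len(nrow(rep$confusions))) {
    cm <- rep$confusions[r, ]
    m <- confusion_metrics(cm$tp, cm$fn, cm$tn, cm$fp)
    expect_equal(unname(m["accuracy"]),
                 100 * (cm$tp + cm$tn) / nrow(sp$holdout))
  }
  # widely separated classes classify the holdout almost perfectly even
  # under train resampling
  expect_gt(rep$metrics$mean[rep$metrics$metric == "accuracy"], 95)
  # holdout identical to train on fully separable data: every metric 100
  sep <- tb
  sep$f1 <- ifelse(sep$asd_outcome, 5, -5) + rnorm(nrow(sep), 0, 0.1)
  perfect <- evaluate_classifier(sep, sep, c("f1", "f2"),
                                 n_repetitions = 5, seed = 2,
                                 resample = FALSE)
  expect_equal(perfect$metrics$mean, rep(100, 6))
  # identical report under the same seed
  rep2 <- evaluate_classifier(sp$train, sp$holdout, c("f1", "f2"),
                              n_repetitions = 30, seed = 2)
  expect_identical(rep$metrics, rep2$metrics)
  # CI bounds bracket the means
  expect_true(all(rep$metrics$ci_lower <= rep$metrics$mean + 1e-9))
  expect_true(all(rep$metrics$ci_upper >= rep$metrics$mean - 1e-9))
})

test_that("a degenerate all-negative predictor yields the documented profile", {
  # train with an uninformative constant feature: the class-weighted SVM
  # on identical points scores near 0; force the all-negative case by
  # making the positive class tiny and the feature constant
  tb <- fixture_feature_table(n = 24, p = 2, seed = 13)
  tb$asd_outcome <- rep(c(FALSE, TRUE), c(20, 4))
  tb$f1 <- c(rep(-1, 20), rep(-1, 4))
  tb$f2 <- 0
  sp <- list(train = tb[c(1:16, 21:22), ], holdout = tb[c(17:20, 23:24), ])
  rep <- evaluate_classifier(sp$train, sp$holdout, c("f1", "f2"),
                             n_repetitions = 5, seed = 3, resample = FALSE)
  cm <- rep$confusions[1, ]
  if (cm$tp + cm$fp == 0) {   # all-negative predictions
    expect_equal(rep$metrics$mean[rep$metrics$metric == "sensitivity"], 0)
    expect_equal(rep$metrics$mean[rep$metrics$metric == "specificity"], 100)
    expect_true(is.nan(rep$metrics$mean[rep$metrics$metric == "ppv"]) ||
                  rep$metrics$n_excluded[rep$metrics$metric == "ppv"] > 0)
  }
})

test_that("shuffle test honours its add-one bounds", {
  tb <- fixture_feature_table(n = 30, p = 2, seed = 14)
  # a metric that is always below any null draw gives p = 1
  st_low <- shuffle_test(-Inf, function(t) 0, tb, n_shuffles = 99, seed = 1)
  expect_equal(st_low$p, 1)
  # a metric above every null draw gives the add-one lower bound
  st_high <- shuffle_test(Inf, function(t) 0, tb, n_shuffles = 999, seed = 1)
  expect_equal(st_high$p, 1 / 1000)
  expect_error(shuffle_test(1, function(t) 0, tb, n_shuffles = 10), "99")
})

test_that("relative error arithmetic and nested elastic net recover signals", {
  # RMSE 10 on a range of 50 is a 20% relative error
  tb <- fixture_feature_table(n = 24, p = 3, seed = 15,
                              beta = c(5, 0, 0), noise_sd = 0)
  r <- elasticnet_nested(tb, features = paste0("f", 1:3),
                         inner_folds = 5, inner_reps = 2, n_boot = 50,
                         seed = 5)
  expect_equal(r$relative_error,
               100 * r$rmse / diff(range(tb$vabs_socialization)))
  # noiseless single-signal model is recovered essentially exactly
  expect_lt(r$rmse, 1e-6 * sd(tb$vabs_socialization))
  expect_true(r$coefficients$always_selected[1])
  expect_error(elasticnet_nested(dplyr::mutate(tb, vabs_socialization = 1),
                                 features = paste0("f", 1:3)),
               "constant")
})

test_that("elastic net ignores features unrelated to the outcome", {
  tb <- fixture_feature_table(n = 40, p = 5, seed = 16, noise_sd = 6)
  r <- elasticnet_nested(tb, features = paste0("f", 1:5),
                         inner_folds = 5, inner_reps = 2, n_boot = 50,
                         seed = 6)
  # pooled RMSE is no better than the intercept-only LOO baseline
  y <- tb$vabs_socialization
  base <- sqrt(mean(vapply(seq_along(y), function(i) {
    (y[i] - mean(y[-i]))^2
  }, numeric(1))))
  expect_gte(r$rmse, 0.95 * base)
})

test_that("bootstrap intervals behave on constants and shrink with n", {
  tb <- fixture_feature_table(n = 40, p = 2, seed = 17)
  ci_const <- bootstrap_ci(function(d) 7.5, tb, n_boot = 50, seed = 1)
  expect_equal(unname(ci_const), c(7.5, 7.5))
  # widening: the mean's interval is wider at n = 20 than at n = 200
  set.seed(18)
  small <- tibble::tibble(x = rnorm(20))
  large <- tibble::tibble(x = rnorm(200))
  ci_s <- bootstrap_ci(function(d) mean(d$x), small, n_boot = 300, seed = 2)
  ci_l <- bootstrap_ci(function(d) mean(d$x), large, n_boot = 300, seed = 2)
  expect_gt(diff(ci_s), diff(ci_l))
  expect_error(bootstrap_ci(function(d) 1, tb[1:5, ]), "at least 10")
})

test_that("standardization inside folds prevents leakage-style inflation", {
  # a leakage-prone variant (standardize on the full sample, select the
  # most separating feature on the full sample, then cross-validate) shows
  # inflated null AUC; the pipeline's fitness stays at chance
  set.seed(19)
  n <- 60; p <- 40
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  tb <- tibble::as_tibble(x)
  tb$subject_id <- sprintf("S%02d", 1:n)
  tb$asd_outcome <- rep(c(FALSE, TRUE), each = n / 2)
  attr(tb, "feature_cols") <- paste0("f", 1:p)
  null_aucs <- vapply(1:10, function(i) {
    t2 <- tb
    t2$asd_outcome <- sample(t2$asd_outcome)
    svm_cv_auc(t2, paste0("f", 1:p), folds = 5, seed = i)
  }, numeric(1))
  leaky_aucs <- vapply(1:10, function(i) {
    t2 <- tb
    t2$asd_outcome <- sample(t2$asd_outcome)
    # leakage: pick the best-separating feature using all labels first
    sep <- vapply(paste0("f", 1:p), function(f) {
      abs(mean(t2[[f]][t2$asd_outcome]) - mean(t2[[f]][!t2$asd_outcome]))
    }, numeric(1))
    svm_cv_auc(t2, names(which.max(sep)), folds = 5, seed = i)
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 0.1)
  expect_gt(mean(leaky_aucs), mean(null_aucs) + 0.05)
})
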