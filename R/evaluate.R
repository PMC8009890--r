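# Holdout evaluation of the classifier and permutation inference.

#' Classification metrics from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN) and accuracy (TP+TN)/n, on the percent scale. A ratio
#' with zero denominator is returned as `NA` (recorded missing).
#'
#' @param tp,fn,tn,fp Confusion-matrix cell counts.
#' @return Named numeric vector of the five metrics in percent.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = ratio(tp + tn, tp + fn + tn + fp))
}

#' Evaluate a classifier on the holdout sample with repetitions
#'
#' For each repetition a class-weighted SVM on the selected features is
#' refit on a stratified bootstrap resample of the train sample and scored
#' on the fixed holdout sample; decision scores are thresholded at the
#' decision boundary (0) for the confusion matrix, and the ROC AUC is
#' computed from the scores. Metrics are reported as mean +/- SD over
#' repetitions on the percent scale with per-repetition 95% confidence
#' intervals averaged over repetitions (Wilson intervals for the
#' proportion metrics, Hanley-McNeil for the AUC). Repetitions where a
#' metric's denominator is zero are excluded from that metric's mean, with
#' the exclusion count reported.
#'
#' @param train,holdout Feature tables from [stratified_split()].
#' @param feature_set Character vector of feature columns to use.
#' @param outcome Binary outcome column name.
#' @param n_repetitions Number of repetitions (default 1000).
#' @param seed Integer seed.
#' @param resample Refit on stratified bootstrap resamples of train
#'   (default) or on the identical train sample every repetition.
#' @param kernel,cost Passed to the SVM.
#' @return A `classifier_report`: list with `metrics` (tibble: metric,
#'   mean, sd, ci_lower, ci_upper, n_excluded), `confusions` (tibble of
#'   per-repetition TP/FN/TN/FP), `feature_set`, and the call settings.
#' @export
evaluate_classifier <- function(train, holdout, feature_set,
                                outcome = "asd_outcome",
                                n_repetitions = 1000, seed = NULL,
                                resample = TRUE,
                                kernel = "linear", cost = 1) {
  if (!length(feature_set)) abort("feature_set must be non-empty")
  y_tr <- as.logical(train[[outcome]])
  y_ho <- as.logical(holdout[[outcome]])
  if (length(unique(y_ho)) < 2L) abort("holdout must contain both classes")
  x_tr <- as.matrix(train[, feature_set, drop = FALSE])
  x_ho <- as.matrix(holdout[, feature_set, drop = FALSE])
  n_pos <- sum(y_ho); n_neg <- sum(!y_ho)

  metric_names <- c("auc", "sensitivity", "specificity", "accuracy",
                    "ppv", "npv")
  vals <- matrix(NA_real_, n_repetitions, 6L,
                 dimnames = list(NULL, metric_names))
  cis <- array(NA_real_, c(n_repetitions, 6L, 2L))
  conf <- matrix(0L, n_repetitions, 4L,
                 dimnames = list(NULL, c("tp", "fn", "tn", "fp")))
  with_seed(seed, {
    for (r in seq_len(n_repetitions)) {
      idx <- if (resample) {
        unlist(lapply(c(FALSE, TRUE), function(cls) {
          i <- which(y_tr == cls)
          i[sample.int(length(i), length(i), replace = TRUE)]
        }))
      } else seq_along(y_tr)
      sc <- svm_scores(x_tr[idx, , drop = FALSE], y_tr[idx], x_ho,
                       kernel, cost)
      pred <- sc > 0
      tp <- sum(pred & y_ho); fn <- sum(!pred & y_ho)
      tn <- sum(!pred & !y_ho); fp <- sum(pred & !y_ho)
      conf[r, ] <- c(tp, fn, tn, fp)
      m <- confusion_metrics(tp, fn, tn, fp)
      a <- 100 * auc_wmw(sc, y_ho)
      vals[r, ] <- c(a, m[c("sensitivity", "specificity", "accuracy",
                            "ppv", "npv")])
      cis[r, 1L, ] <- 100 * hanley_mcneil_ci(a / 100, n_pos, n_neg)
      cis[r, 2L, ] <- 100 * wilson_ci(tp, tp + fn)
      cis[r, 3L, ] <- 100 * wilson_ci(tn, tn + fp)
      cis[r, 4L, ] <- 100 * wilson_ci(tp + tn, length(y_ho))
      cis[r, 5L, ] <- 100 * wilson_ci(tp, tp + fp)
      cis[r, 6L, ] <- 100 * wilson_ci(tn, tn + fn)
    }
  })
  metrics <- tibble(
    metric = metric_names,
    mean = unname(apply(vals, 2L, mean, na.rm = TRUE)),
    sd = unname(apply(vals, 2L, sd, na.rm = TRUE)),
    ci_lower = unname(apply(cis[, , 1L, drop = FALSE], 2L, mean,
                            na.rm = TRUE)),
    ci_upper = unname(apply(cis[, , 2L, drop = FALSE], 2L, mean,
                            na.rm = TRUE)),
    n_excluded = unname(apply(vals, 2L, function(v) sum(is.na(v))))
  )
  structure(
    list(metrics = metrics, confusions = as_tibble(conf),
         feature_set = feature_set,
         settings = list(n_repetitions = n_repetitions, seed = seed,
                         resample = resample, kernel = kernel, cost = cost)),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d repetitions, features: %s\n",
              x$settings$n_repetitions,
              paste(x$feature_set, collapse = ", ")))
  print(x$metrics)
  invisible(x)
}

#' @rdname evaluate_classifier
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @export
tidy.classifier_report <- function(x, ...) x$metrics

#' @rdname evaluate_classifier
#' @export
glance.classifier_report <- function(x, ...) {
  m <- x$metrics
  as_tibble(setNames(as.list(m$mean), m$metric)) |>
    mutate(n_repetitions = x$settings$n_repetitions,
           n_features = length(x$feature_set))
}

#' Permutation (shuffle) test of a performance metric
#'
#' Permutes the outcome labels `n_shuffles` times, recomputes the metric
#' with `refit` on each permuted table, and returns the one-sided
#' add-one-corrected p-value `(1 + #(null >= observed)) / (n_shuffles + 1)`.
#' For comparing two classifiers, pass their metric difference as the
#' observed value and a `refit` that returns the difference under
#' permutation.
#'
#' @param observed Observed metric value.
#' @param refit Function taking a (permuted) feature table and returning
#'   the metric.
#' @param table Feature table.
#' @param outcome Outcome column to permute.
#' @param n_shuffles Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A `shuffle_test` list: `p`, `observed`, `null` (numeric vector).
#' @export
shuffle_test <- function(observed, refit, table, outcome = "asd_outcome",
                         n_shuffles = 999, seed = NULL) {
  if (n_shuffles < 99) abort("use at least 99 shuffles")
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      tt <- table
      tt[[outcome]] <- tt[[outcome]][sample.int(nrow(tt))]
      refit(tt)
    }, numeric(1))
  })
  structure(list(p = (1 + sum(null >= observed)) / (n_shuffles + 1),
                 observed = observed, null = null,
                 n_shuffles = n_shuffles),
            class = "shuffle_test")
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat(sprintf("<shuffle_test> observed %.4f, p = %.4g (%d shuffles)\n",
              x$observed, x$p, x$n_shuffles))
  invisible(x)
}

#' Bootstrap percentile confidence interval
#'
#' Percentile interval of a statistic over subject-level resamples with
#' replacement.
#'
#' @param statistic Function taking a resampled table and returning a
#'   scalar.
#' @param table Data frame of subject-level rows.
#' @param n_boot Number of resamples (default 1000).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(statistic, table, n_boot = 1000, level = 0.95,
                         seed = NULL) {
  if (nrow(table) < 10L) abort("bootstrap needs at least 10 rows")
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      statistic(table[sample.int(nrow(table), nrow(table),
                                 replace = TRUE), , drop = FALSE])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  setNames(quantile(reps, c(a, 1 - a), names = FALSE, type = 7),
           c("lower", "upper"))
}
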