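# Dimensional-outcome prediction: elastic-net regression with
# leave-one-out outer cross-validation and nested repeated k-fold inner
# tuning of the mixing and penalty parameters.

# Inner tuning on one outer-training set: repeated k-fold CV over the
# alpha x lambda grid, minimizing mean RMSE; exact ties go to the sparser
# model (larger lambda, then larger alpha). The lambda grid is anchored at
# the data-driven lambda_max for each alpha, log-spaced down to
# 1e-3 * lambda_max, plus an exact 0 (the OLS limit, valid at n > p).
tune_enet <- function(x, y, alphas, n_lambda, inner_folds, inner_reps) {
  n <- nrow(x)
  lmax0 <- max(abs(crossprod(x, y - mean(y)))) / n
  grids <- lapply(alphas, function(a) {
    c(lmax0 / max(a, 1e-3) * exp(seq(0, log(1e-3), length.out = n_lambda)), 0)
  })
  rmse_sum <- lapply(grids, function(g) numeric(length(g)))
  for (rep in seq_len(inner_reps)) {
    fold <- rep_len(seq_len(inner_folds), n)[sample.int(n)]
    for (f in seq_len(inner_folds)) {
      te <- fold == f
      xtr <- x[!te, , drop = FALSE]; ytr <- y[!te]
      xte <- cbind(1, x[te, , drop = FALSE]); yte <- y[te]
      for (ai in seq_along(alphas)) {
        fit <- glmnet::glmnet(xtr, ytr, alpha = alphas[ai],
                              lambda = grids[[ai]], standardize = FALSE)
        # user-supplied lambda sequences are fitted in full; predicting by
        # hand from the coefficient path avoids predict()'s S4 dispatch
        pr <- if (length(fit$lambda) == length(grids[[ai]])) {
          xte %*% rbind(fit$a0, as.matrix(fit$beta))
        } else {
          predict(fit, x[te, , drop = FALSE], s = grids[[ai]])
        }
        rmse_sum[[ai]] <- rmse_sum[[ai]] +
          sqrt(colMeans((pr - yte)^2))
      }
    }
  }
  best <- list(rmse = Inf, alpha = NA_real_, lambda = NA_real_)
  for (ai in seq_along(alphas)) {
    m <- rmse_sum[[ai]] / (inner_folds * inner_reps)
    # grid is ordered lambda-descending: the first minimum is the sparsest
    j <- which.min(m)
    if (m[j] < best$rmse - 1e-12 ||
        (abs(m[j] - best$rmse) <= 1e-12 && alphas[ai] > best$alpha)) {
      best <- list(rmse = m[j], alpha = alphas[ai], lambda = grids[[ai]][j])
    }
  }
  best
}

#' Elastic-net prediction of a continuous outcome with nested CV
#'
#' Outer loop: leave-one-out over subjects. For every outer fold, features
#' are standardized with the training-fold statistics only, the mixing
#' parameter and penalty strength are tuned by repeated inner k-fold
#' cross-validation minimizing RMSE (ties to the sparser model), and the
#' refit model predicts the held-out subject. Outer predictions are pooled
#' into the RMSE and the relative error (RMSE divided by the outcome range,
#' in percent). Coefficients are recorded per outer fold in standard
#' units; a feature is "always selected" if its coefficient is nonzero in
#' every fold. The 95% RMSE confidence interval is a subject-level
#' bootstrap over the pooled (observed, predicted) pairs.
#'
#' @param table Feature table.
#' @param outcome Continuous outcome column (default
#'   `"vabs_socialization"`).
#' @param features Feature columns (default: the table's feature columns).
#' @param inner_folds,inner_reps Inner CV structure (default 10-fold, 10
#'   repeats).
#' @param alphas Elastic-net mixing grid (default 0.1..1 by 0.1).
#' @param n_lambda Log-spaced penalties per alpha (plus the OLS limit 0).
#' @param n_boot Bootstrap resamples for the RMSE interval.
#' @param seed Integer seed.
#' @return A `regression_report`: list with `rmse`, `rmse_ci`,
#'   `relative_error` (percent), `predictions` (tibble), `coefficients`
#'   (tibble: feature, mean_coef, sd_coef, always_selected), and settings.
#' @export
elasticnet_nested <- function(table, outcome = "vabs_socialization",
                              features = NULL, inner_folds = 10,
                              inner_reps = 10,
                              alphas = seq(0.1, 1, by = 0.1),
                              n_lambda = 10, n_boot = 1000, seed = NULL) {
  feats <- feature_cols_of(table, features)
  y <- table[[outcome]]
  if (anyNA(y)) abort("outcome contains missing values")
  if (sd(y) == 0) abort("outcome is constant")
  n <- nrow(table)
  if (n < 20L) abort("need at least 20 subjects for nested cross-validation")
  if (n - 1L < inner_folds) abort("too few subjects for the inner folds")
  x_all <- as.matrix(table[, feats, drop = FALSE])
  seeds <- child_seeds(seed %||% sample.int(2^30, 1L), n + 1L)

  preds <- numeric(n)
  coefs <- matrix(NA_real_, n, length(feats),
                  dimnames = list(NULL, feats))
  chosen <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("alpha", "lambda")))
  for (i in seq_len(n)) {
    x_tr <- x_all[-i, , drop = FALSE]
    y_tr <- y[-i]
    mu <- colMeans(x_tr)
    sdv <- apply(x_tr, 2L, sd)
    sdv[sdv == 0] <- 1
    xs <- sweep(sweep(x_tr, 2L, mu), 2L, sdv, "/")
    xn <- (x_all[i, ] - mu) / sdv
    best <- with_seed(seeds[i],
                      tune_enet(xs, y_tr, alphas, n_lambda,
                                inner_folds, inner_reps))
    if (best$lambda == 0 && nrow(xs) > ncol(xs) + 1L) {
      # the lambda = 0 limit is ordinary least squares: use the exact
      # solver rather than coordinate descent, which loses precision on
      # near-saturated designs
      ls <- stats::lm.fit(cbind(1, xs), y_tr)
      cf <- ifelse(is.na(ls$coefficients), 0, ls$coefficients)
      preds[i] <- sum(cf * c(1, xn))
      coefs[i, ] <- cf[-1L]
    } else {
      lam_seq <- if (best$lambda > 0) c(best$lambda * 2, best$lambda) else {
        c(max(abs(crossprod(xs, y_tr - mean(y_tr)))) / nrow(xs) * 1e-3, 0)
      }
      fit <- glmnet::glmnet(xs, y_tr, alpha = best$alpha, lambda = lam_seq,
                            standardize = FALSE, thresh = 1e-12)
      preds[i] <- predict(fit, matrix(xn, 1L), s = best$lambda)[1L]
      coefs[i, ] <- as.numeric(stats::coef(fit, s = best$lambda))[-1L]
    }
    chosen[i, ] <- c(best$alpha, best$lambda)
  }
  resid <- y - preds
  rmse <- sqrt(mean(resid^2))
  rng <- max(y) - min(y)
  pred_tbl <- tibble(subject_id = table$subject_id %||% seq_len(n),
                     observed = y, predicted = preds)
  ci <- bootstrap_ci(function(d) sqrt(mean((d$observed - d$predicted)^2)),
                     pred_tbl, n_boot = n_boot, seed = seeds[n + 1L])
  structure(
    list(rmse = rmse, rmse_ci = ci,
         relative_error = 100 * rmse / rng,
         outcome_range = rng,
         predictions = pred_tbl,
         coefficients = tibble(
           feature = feats,
           mean_coef = colMeans(coefs),
           sd_coef = apply(coefs, 2L, sd),
           always_selected = apply(coefs != 0, 2L, all)),
         chosen = as_tibble(chosen),
         settings = list(outcome = outcome, inner_folds = inner_folds,
                         inner_reps = inner_reps, alphas = alphas,
                         n_lambda = n_lambda, seed = seed)),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> LOO RMSE %.3f (95%% CI %.3f-%.3f), relative error %.1f%% of range %.1f\n",
    x$rmse, x$rmse_ci["lower"], x$rmse_ci["upper"], x$relative_error,
    x$outcome_range))
  always <- x$coefficients |> filter(.data$always_selected)
  if (nrow(always)) {
    cat("always-selected features:\n")
    print(always)
  }
  invisible(x)
}

#' @rdname elasticnet_nested
#' @param x A `regression_report`.
#' @param ... Unused.
#' @export
tidy.regression_report <- function(x, ...) x$coefficients

#' @rdname elasticnet_nested
#' @export
glance.regression_report <- function(x, ...) {
  tibble(rmse = x$rmse, rmse_ci_lower = x$rmse_ci[["lower"]],
         rmse_ci_upper = x$rmse_ci[["upper"]],
         relative_error = x$relative_error,
         n = nrow(x$predictions),
         n_always_selected = sum(x$coefficients$always_selected))
}
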