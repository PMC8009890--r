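# Categorical-outcome prediction: stratified splitting, class-weighted SVM
# with cross-validated AUC, genetic-algorithm feature selection, holdout
# evaluation and permutation (shuffle) inference.

#' Stratified train/holdout split
#'
#' Splits subjects into a main (train) and holdout sample preserving the
#' outcome class proportions. The train size is `round(train_fraction * n)`
#' apportioned across classes by largest remainder, so a 91-subject cohort
#' at 0.7 yields the 64/27 partition.
#'
#' @param table Feature table (one row per subject).
#' @param train_fraction Fraction for the train sample (default 0.7),
#'   strictly between 0 and 1.
#' @param outcome Name of the binary outcome column.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `holdout` (disjoint, exhaustive).
#' @export
stratified_split <- function(table, train_fraction = 0.7,
                             outcome = "asd_outcome", seed = NULL) {
  y <- table[[outcome]]
  if (length(unique(y)) < 2L) abort("both outcome classes must be present")
  if (any(table(y) < 2L)) abort("each outcome class needs at least 2 members")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be strictly between 0 and 1 (no empty partition)")
  }
  with_seed(seed, {
    classes <- sort(unique(y))
    counts <- as.integer(table(factor(y, levels = classes)))
    n_train <- apportion(counts, round(train_fraction * nrow(table)))
    take <- unlist(mapply(function(cls, k) {
      idx <- which(y == cls)
      idx[sample.int(length(idx), k)]
    }, classes, n_train, SIMPLIFY = FALSE))
    take <- sort(take)
    list(train = table[take, , drop = FALSE],
         holdout = table[-take, , drop = FALSE])
  })
}

# Fit a class-weighted linear (or RBF) SVM on standardized features and
# return decision scores for new data, oriented so larger = positive class.
svm_scores <- function(x_train, y_train, x_new, kernel = "linear", cost = 1) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2L, sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x_train, 2L, mu), 2L, sdv, "/")
  xn <- sweep(sweep(x_new, 2L, mu), 2L, sdv, "/")
  yf <- factor(y_train, levels = c(FALSE, TRUE))
  w <- length(yf) / (2 * table(yf))
  fit <- e1071::svm(xs, yf, kernel = kernel, cost = cost, scale = FALSE,
                    class.weights = w)
  dv <- attr(predict(fit, xn, decision.values = TRUE), "decision.values")
  # libsvm orients decision values toward the first label it encountered;
  # flip so that larger scores always mean the positive (TRUE) class.
  if (startsWith(colnames(dv)[1L], "FALSE")) -dv[, 1L] else dv[, 1L]
}

#' Cross-validated SVM AUC of a feature subset
#'
#' Fitness measure of the genetic algorithm: the ROC AUC of pooled
#' decision scores from a stratified k-fold cross-validated class-weighted
#' SVM built on the selected features. Standardization uses training-fold
#' statistics only; class weights are inversely proportional to class
#' frequency. If a drawn fold lacks both classes the folds are re-drawn
#' (bounded retries).
#'
#' @param train Feature table.
#' @param features Character vector (or logical mask over the table's
#'   feature columns) selecting at least one feature.
#' @param outcome Binary outcome column name.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold draw.
#' @param kernel SVM kernel (default `"linear"`).
#' @param cost SVM misclassification cost.
#' @return AUC as a fraction in \[0, 1\].
#' @export
svm_cv_auc <- function(train, features, outcome = "asd_outcome", folds = 10,
                       seed = NULL, kernel = "linear", cost = 1) {
  all_feats <- feature_cols_of(train)
  if (is.logical(features)) features <- all_feats[features]
  if (!length(features)) abort("at least one feature must be selected")
  x <- as.matrix(train[, features, drop = FALSE])
  y <- as.logical(train[[outcome]])
  with_seed(seed, {
    for (try in 1:25) {
      fold <- stratified_folds(y, folds)
      ok <- all(vapply(seq_len(folds), function(f) {
        length(unique(y[fold != f])) == 2L
      }, logical(1)))
      if (ok) break
      if (try == 25) abort("could not draw folds with both classes in every training fold")
    }
    scores <- numeric(length(y))
    for (f in seq_len(folds)) {
      te <- fold == f
      if (!any(te)) next
      scores[te] <- svm_scores(x[!te, , drop = FALSE], y[!te],
                               x[te, , drop = FALSE], kernel, cost)
    }
    auc_wmw(scores, y)
  })
}

#' Genetic-algorithm parameters
#'
#' @param population_size Number of masks per generation.
#' @param n_generations Maximum generations per evolution.
#' @param crossover_prob Uniform-crossover probability.
#' @param mutation_prob Per-bit mutation probability (default 1/n set at
#'   run time when `NULL`).
#' @param elitism_count Masks copied unchanged to the next generation.
#' @param n_evolutions Independent GA runs for the incidence analysis.
#' @param auc_threshold Fitness an evolution's best set must exceed to
#'   enter the incidence pool (default 0.75).
#' @param incidence_threshold Incidence above which a feature joins the
#'   high-incidence set (default 0.80).
#' @param cv_folds Folds of the SVM fitness (default 10).
#' @param patience Stop an evolution early after this many generations
#'   without improvement.
#' @param parsimony Per-feature fitness penalty used only to break ties
#'   toward sparser masks (default 1e-4).
#' @param seed Integer seed.
#' @return A `ga_params` list.
#' @export
ga_params <- function(population_size = 20, n_generations = 25,
                      crossover_prob = 0.8, mutation_prob = NULL,
                      elitism_count = 2, n_evolutions = 20,
                      auc_threshold = 0.75, incidence_threshold = 0.80,
                      cv_folds = 10, patience = 8, parsimony = 1e-4,
                      seed = NULL) {
  stopifnot(crossover_prob >= 0, crossover_prob <= 1,
            auc_threshold > 0, auc_threshold < 1,
            incidence_threshold > 0, incidence_threshold < 1)
  structure(list(population_size = population_size,
                 n_generations = n_generations,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism_count = elitism_count, n_evolutions = n_evolutions,
                 auc_threshold = auc_threshold,
                 incidence_threshold = incidence_threshold,
                 cv_folds = cv_folds, patience = patience,
                 parsimony = parsimony, seed = seed),
            class = "ga_params")
}

# One GA evolution over binary feature masks. Fitness values are memoized
# across generations (masks recur constantly); the fold seed is fixed per
# evolution so fitness is a deterministic function of the mask.
ga_evolve <- function(x_fit, params, n_feat) {
  pop_n <- params$population_size
  mut_p <- params$mutation_prob %||% (1 / n_feat)
  memo <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    if (!any(mask)) return(-Inf)
    key <- paste(which(mask), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- x_fit(mask) - params$parsimony * sum(mask)
    memo[[key]] <- v
    v
  }
  pop <- matrix(runif(pop_n * n_feat) < 0.5, pop_n)
  pop[rowSums(pop) == 0, sample.int(n_feat, 1L)] <- TRUE
  fit <- apply(pop, 1L, fitness)
  best_fit <- -Inf; best_mask <- pop[1L, ]; stale <- 0L
  for (gen in seq_len(params$n_generations)) {
    gb <- which.max(fit)
    if (fit[gb] > best_fit + 1e-12) {
      best_fit <- fit[gb]; best_mask <- pop[gb, ]; stale <- 0L
    } else stale <- stale + 1L
    if (stale >= params$patience) break
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(min(params$elitism_count, pop_n))], ,
                 drop = FALSE]
    # binary tournament selection
    pick <- function() {
      ij <- sample.int(pop_n, 2L)
      pop[ij[which.max(fit[ij])], ]
    }
    children <- matrix(FALSE, pop_n - nrow(elite), n_feat)
    for (i in seq_len(nrow(children))) {
      p1 <- pick(); p2 <- pick()
      child <- if (runif(1) < params$crossover_prob) {
        sel <- runif(n_feat) < 0.5
        ifelse(sel, p1, p2)
      } else p1
      flip <- runif(n_feat) < mut_p
      child <- xor(child, flip)
      if (!any(child)) child[sample.int(n_feat, 1L)] <- TRUE
      children[i, ] <- child
    }
    pop <- rbind(elite, children)
    fit <- apply(pop, 1L, fitness)
  }
  gb <- which.max(fit)
  if (fit[gb] > best_fit) { best_fit <- fit[gb]; best_mask <- pop[gb, ] }
  # report the raw AUC (strip the parsimony term)
  list(mask = best_mask, auc = best_fit + params$parsimony * sum(best_mask))
}

#' Genetic-algorithm feature selection with SVM fitness
#'
#' Evolves binary feature masks with the cross-validated SVM AUC as
#' fitness, repeated over `n_evolutions` independent runs. Returns the
#' best mask overall (the optimal set), the per-feature incidence — the
#' fraction of evolutions whose best set exceeded `auc_threshold` that
#' contain the feature — and the high-incidence set (incidence above
#' `incidence_threshold`). If no evolution clears the AUC threshold the
#' incidence is computed over all best-per-evolution sets, with a warning.
#'
#' @param train Feature table (train sample).
#' @param params A [ga_params()].
#' @param outcome Binary outcome column name.
#' @param features Candidate feature columns (default: the table's feature
#'   columns).
#' @return A `ga_selection`: list with `optimal_set`, `optimal_auc`,
#'   `incidence` (tibble), `high_incidence_set`, `evolutions` (tibble of
#'   per-run best AUC and mask).
#' @export
ga_select <- function(train, params = ga_params(), outcome = "asd_outcome",
                      features = NULL) {
  feats <- feature_cols_of(train, features)
  n_feat <- length(feats)
  if (n_feat < 2L) abort("feature selection needs at least 2 candidate features")
  seeds <- child_seeds(params$seed %||% sample.int(2^30, 1L),
                       2L * params$n_evolutions)
  runs <- vector("list", params$n_evolutions)
  for (ev in seq_len(params$n_evolutions)) {
    fold_seed <- seeds[2L * ev - 1L]
    x_fit <- function(mask) {
      svm_cv_auc(train, feats[mask], outcome = outcome,
                 folds = params$cv_folds, seed = fold_seed)
    }
    runs[[ev]] <- with_seed(seeds[2L * ev],
                            ga_evolve(x_fit, params, n_feat))
  }
  aucs <- map_dbl(runs, "auc")
  masks <- do.call(rbind, map(runs, "mask"))
  elite <- aucs > params$auc_threshold
  if (!any(elite)) {
    warn(sprintf(
      "no evolution reached the AUC threshold %.2f; incidence computed over all best-per-evolution sets",
      params$auc_threshold))
    elite <- rep(TRUE, length(aucs))
  }
  incidence <- colMeans(masks[elite, , drop = FALSE])
  best <- which.max(aucs)
  structure(
    list(optimal_set = feats[masks[best, ]],
         optimal_auc = aucs[best],
         incidence = tibble(feature = feats, incidence = unname(incidence)),
         high_incidence_set = feats[incidence > params$incidence_threshold],
         evolutions = tibble(evolution = seq_along(aucs), best_auc = aucs,
                             mask = map(seq_along(aucs), ~masks[.x, ])),
         params = params),
    class = "ga_selection")
}

#' @export
print.ga_selection <- function(x, ...) {
  cat(sprintf("<ga_selection> optimal set (AUC %.3f): %s\n",
              x$optimal_auc, paste(x$optimal_set, collapse = ", ")))
  cat(sprintf("high-incidence set (> %.0f%%): %s\n",
              100 * x$params$incidence_threshold,
              paste(x$high_incidence_set, collapse = ", ")))
  invisible(x)
}

#' @rdname ga_select
#' @param x A `ga_selection`.
#' @param ... Unused.
#' @export
tidy.ga_selection <- function(x, ...) x$incidence
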