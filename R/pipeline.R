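# End-to-end pipeline: simulate (or ingest) -> inclusion -> Nc features ->
# map learning -> template fitting -> feature extraction -> classification
# and regression, with a manifest for re-running any stage.

#' Pipeline configuration
#'
#' Bundles every stage's parameters and seeds. Windows default to the
#' standard analysis windows: Nc 300-800 ms, microstate clustering
#' 0-794 ms, microstate features 300-794 ms. Any seed left `NULL` is
#' auto-filled from `seed` and recorded in the resolved configuration.
#'
#' @param sim A [sim_config()] for the synthetic cohort (the pipeline's
#'   `simulate` mode), or `NULL` when ingesting files via `erp_dir`.
#' @param erp_dir Directory of ERP CSV/JSON pairs (ignored when `sim` is
#'   given).
#' @param subjects_file CSV of subject covariates and outcomes (ignored
#'   when `sim` is given).
#' @param montage_file JSON montage path, or `NULL` for the default
#'   synthetic-layout montage.
#' @param nc_window,cluster_window,feature_window Analysis windows (ms).
#' @param reference_group,reference_condition Reference subset for map
#'   learning.
#' @param k_range Candidate map counts.
#' @param n_splits,n_rand Map-selection cross-validation settings.
#' @param ignore_polarity Polarity mode for all topographic matching.
#' @param min_trials Inclusion threshold.
#' @param train_fraction Classifier train fraction.
#' @param ga A [ga_params()].
#' @param n_repetitions Classifier evaluation repetitions.
#' @param n_shuffles Shuffle-test permutations.
#' @param inner_folds,inner_reps Elastic-net inner CV structure.
#' @param n_boot Bootstrap resamples for the RMSE interval.
#' @param seed Master seed used to fill any unset stage seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            erp_dir = NULL, subjects_file = NULL,
                            montage_file = NULL,
                            nc_window = c(300, 800),
                            cluster_window = c(0, 794),
                            feature_window = c(300, 794),
                            reference_group = "noFH-noASD",
                            reference_condition = "FD",
                            k_range = 2:7, n_splits = 10, n_rand = 200,
                            ignore_polarity = FALSE,
                            min_trials = 10, train_fraction = 0.7,
                            ga = ga_params(), n_repetitions = 1000,
                            n_shuffles = 199,
                            inner_folds = 10, inner_reps = 10,
                            n_boot = 1000, seed = 1) {
  epoch <- if (!is.null(sim)) sim$epoch else c(-200, 794)
  for (w in list(cluster_window, feature_window)) {
    if (w[1] < epoch[1] || w[1] > w[2]) {
      abort("analysis windows must be ordered and start inside the epoch")
    }
  }
  if (feature_window[1] < cluster_window[1] ||
      feature_window[2] > cluster_window[2]) {
    abort("feature window must lie inside the clustering window")
  }
  seeds <- child_seeds(seed, 6L)
  ga$seed <- ga$seed %||% seeds[3L]
  structure(
    list(sim = sim, erp_dir = erp_dir, subjects_file = subjects_file,
         montage_file = montage_file,
         nc_window = nc_window, cluster_window = cluster_window,
         feature_window = feature_window,
         reference_group = reference_group,
         reference_condition = reference_condition,
         k_range = k_range, n_splits = n_splits, n_rand = n_rand,
         ignore_polarity = ignore_polarity,
         min_trials = min_trials, train_fraction = train_fraction,
         ga = ga, n_repetitions = n_repetitions, n_shuffles = n_shuffles,
         inner_folds = inner_folds, inner_reps = inner_reps,
         n_boot = n_boot, seed = seed,
         stage_seeds = list(select = seeds[1L], split = seeds[2L],
                            ga = ga$seed, evaluate = seeds[4L],
                            shuffle = seeds[5L], enet = seeds[6L])),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the defaults of
#' [pipeline_config()]; nested `sim` and `ga` blocks override the
#' corresponding constructor defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$ga)) args$ga <- do.call(ga_params, raw$ga)
  for (w in intersect(c("nc_window", "cluster_window", "feature_window",
                        "k_range"), names(args))) {
    args[[w]] <- as.numeric(unlist(args[[w]]))
  }
  do.call(pipeline_config, args)
}

read_erp_dir <- function(erp_dir) {
  files <- sort(list.files(erp_dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) abort(sprintf("no ERP CSV files in %s", erp_dir))
  lst <- map(files, read_erp)
  tibble(subject_id = map_chr(lst, "subject_id"),
         condition = map_chr(lst, "condition"),
         erp = lst)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, the minimal-trial inclusion filter, Nc
#' feature extraction, microstate map learning on the reference group and
#' condition, template fitting and feature extraction for all subjects,
#' genetic-algorithm classification of the binary outcome on the
#' family-history subsample, and elastic-net regression of the
#' socialization score on the full included sample. All stage outputs are
#' written under `out_dir` together with a manifest (resolved
#' configuration, package version, per-file checksums) sufficient to
#' re-run any stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param classify_groups Groups entering the classifier stage (default
#'   the two family-history groups).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("erpstates-run-"),
                         classify_groups = c("FH-noASD", "FH-ASD")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # -- ingest or simulate ---------------------------------------------------
  if (!is.null(config$sim)) {
    cohort <- stage("simulate", simulate_cohort(config$sim,
                                                feature_window = config$feature_window))
    subjects <- cohort$subjects
    erps <- cohort$erps
  } else {
    erps <- stage("ingest", read_erp_dir(config$erp_dir))
    subjects <- as_tibble(utils::read.csv(config$subjects_file))
    cohort <- NULL
  }

  # -- inclusion ------------------------------------------------------------
  subjects <- stage("inclusion", apply_inclusion(subjects, config$min_trials))
  erps <- erps |> filter(.data$subject_id %in% subjects$subject_id)

  # -- Nc features ----------------------------------------------------------
  mont <- if (!is.null(config$montage_file)) {
    read_montage(config$montage_file)
  } else {
    default_montage(nrow(erps$erp[[1L]]$data))
  }
  nc <- stage("nc", nc_features(erps, mont, window = config$nc_window))
  nc_diff <- nc_difference_scores(nc)

  # -- microstate map learning ---------------------------------------------
  ref_ids <- subjects$subject_id[subjects$group == config$reference_group]
  ref_erps <- erps |>
    filter(.data$subject_id %in% ref_ids,
           .data$condition == config$reference_condition)
  model <- stage("select_n_maps", select_n_maps(
    ref_erps, k_range = config$k_range, window = config$cluster_window,
    n_splits = config$n_splits, n_rand = config$n_rand,
    ignore_polarity = config$ignore_polarity,
    seed = config$stage_seeds$select))

  # -- template fitting and features ---------------------------------------
  feats <- stage("features", microstate_features(
    erps, model$maps, feature_window = config$feature_window,
    fit_window = config$cluster_window,
    ignore_polarity = config$ignore_polarity))
  ftable <- stage("feature_table", build_feature_table(feats, subjects))

  # -- classification (family-history subsample) ----------------------------
  cls_table <- ftable |>
    semi_join(subjects |> filter(.data$group %in% classify_groups),
              by = "subject_id")
  attr(cls_table, "feature_cols") <- attr(ftable, "feature_cols")
  split <- stage("split", stratified_split(cls_table, config$train_fraction,
                                           seed = config$stage_seeds$split))
  sel <- stage("ga_select", ga_select(split$train, config$ga))
  eval_set <- if (length(sel$high_incidence_set)) {
    sel$high_incidence_set
  } else sel$optimal_set
  reports <- list(
    high_incidence = stage("evaluate", evaluate_classifier(
      split$train, split$holdout, eval_set,
      n_repetitions = config$n_repetitions,
      seed = config$stage_seeds$evaluate)),
    optimal = stage("evaluate", evaluate_classifier(
      split$train, split$holdout, sel$optimal_set,
      n_repetitions = config$n_repetitions,
      seed = config$stage_seeds$evaluate)))
  obs_auc <- reports$high_incidence$metrics$mean[
    reports$high_incidence$metrics$metric == "auc"] / 100
  auc_of <- function(tt) {
    sp <- stratified_split(tt, config$train_fraction,
                           seed = config$stage_seeds$split)
    sc <- svm_scores(as.matrix(sp$train[, eval_set, drop = FALSE]),
                     as.logical(sp$train$asd_outcome),
                     as.matrix(sp$holdout[, eval_set, drop = FALSE]))
    auc_wmw(sc, as.logical(sp$holdout$asd_outcome))
  }
  cls_shuffle <- stage("shuffle", shuffle_test(
    obs_auc, auc_of, cls_table, n_shuffles = config$n_shuffles,
    seed = config$stage_seeds$shuffle))

  # -- regression (full included sample) ------------------------------------
  reg_table <- ftable |> filter(!is.na(.data$vabs_socialization))
  attr(reg_table, "feature_cols") <- attr(ftable, "feature_cols")
  regression <- stage("elasticnet", elasticnet_nested(
    reg_table, inner_folds = config$inner_folds,
    inner_reps = config$inner_reps, n_boot = config$n_boot,
    seed = config$stage_seeds$enet))

  # -- outputs and manifest -------------------------------------------------
  paths <- list(
    subjects = file.path(out_dir, "subjects.csv"),
    nc = file.path(out_dir, "nc_features.csv"),
    nc_diff = file.path(out_dir, "nc_difference_scores.csv"),
    maps = file.path(out_dir, "maps.csv"),
    features = file.path(out_dir, "microstate_features.csv"),
    feature_table = file.path(out_dir, "feature_table.csv"),
    incidence = file.path(out_dir, "incidence.csv"),
    classifier = file.path(out_dir, "classifier_report.json"),
    regression = file.path(out_dir, "regression_report.json"),
    coefficients = file.path(out_dir, "coefficients.csv"))
  write.csv(subjects, paths$subjects, row.names = FALSE)
  write.csv(nc, paths$nc, row.names = FALSE)
  write.csv(nc_diff, paths$nc_diff, row.names = FALSE)
  write_maps(model$maps, paths$maps)
  write.csv(feats, paths$features, row.names = FALSE)
  write.csv(ftable, paths$feature_table, row.names = FALSE)
  write.csv(sel$incidence, paths$incidence, row.names = FALSE)
  jsonlite::write_json(list(
    k_opt = model$k_opt,
    ev = model$ev,
    optimal_set = sel$optimal_set,
    high_incidence_set = sel$high_incidence_set,
    evaluated_set = eval_set,
    metrics = list(high_incidence = reports$high_incidence$metrics,
                   optimal = reports$optimal$metrics),
    auc_shuffle_p = cls_shuffle$p,
    seeds = config$stage_seeds),
    paths$classifier, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(
    rmse = regression$rmse,
    rmse_ci = as.list(regression$rmse_ci),
    relative_error = regression$relative_error,
    outcome_range = regression$outcome_range,
    seeds = config$stage_seeds),
    paths$regression, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(regression$coefficients, paths$coefficients, row.names = FALSE)

  manifest <- list(
    package_version = as.character(packageVersion("erpstates")),
    created = format(Sys.time(), tz = "UTC"),
    config = config,
    checksums = as.list(tools::md5sum(unlist(paths))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  invisible(list(cohort = cohort, subjects = subjects, nc = nc,
                 nc_diff = nc_diff, model = model, features = feats,
                 feature_table = ftable, split = split, selection = sel,
                 reports = reports, auc_shuffle = cls_shuffle,
                 regression = regression, out_dir = out_dir,
                 manifest = manifest))
}
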