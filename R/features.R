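# Assembly of the subject-level machine-learning feature table.

#' Extract microstate features for every subject and condition
#'
#' Fits the template maps to each ERP and extracts per-map duration and
#' mean GFP inside the feature window.
#'
#' @param erps Tibble with `subject_id`, `condition` and an `erp`
#'   list-column, or a list of [erp_waveform()] objects.
#' @param maps An [ms_maps()] template set.
#' @param feature_window Feature window in ms (default 300-794).
#' @param fit_window Window over which templates are fitted (default
#'   0-794); the feature window must lie inside it.
#' @param ignore_polarity Match on absolute correlation?
#' @return Tidy tibble: one row per subject x condition x map with
#'   `duration_ms`, `mean_gfp`, `present`.
#' @export
microstate_features <- function(erps, maps, feature_window = c(300, 794),
                                fit_window = c(0, 794),
                                ignore_polarity = FALSE) {
  lst <- as_erp_list(erps)
  bind_rows(map(lst, function(e) {
    seg <- fit_templates(e, maps, fit_window, ignore_polarity = ignore_polarity)
    extract_features(seg, feature_window = feature_window) |>
      mutate(subject_id = e$subject_id, condition = e$condition,
             .before = 1L)
  }))
}

#' Build the subject-level feature table for outcome prediction
#'
#' Joins microstate features (wide: duration and mean GFP per retained map
#' and condition) with subject covariates and outcomes. A map is "present
#' in a subject" if its duration exceeds zero in any condition; maps absent
#' in more than `absence_drop` of subjects are dropped from the feature set
#' (they were only found in a subset of the cohort). Missing mean GFP for
#' an absent map is imputed as 0. Sex is coded 0/1 (F/M). With 3 retained
#' maps, 3 conditions and the 3 covariates this yields the 21-column
#' design.
#'
#' @param features Tidy tibble from [microstate_features()].
#' @param subjects Subject tibble with covariates and outcomes.
#' @param covariates Covariate columns to include.
#' @param absence_drop Drop a map absent in more than this fraction of
#'   subjects (default 0.05).
#' @return A tibble with `subject_id`, feature columns, and the outcome
#'   columns `asd_outcome` and (if available) `vabs_socialization`. The
#'   feature column names are recorded in `attr(., "feature_cols")`;
#'   dropped maps in `attr(., "dropped_maps")`.
#' @export
build_feature_table <- function(features, subjects,
                                covariates = c("sex", "age_days",
                                               "msel_composite"),
                                absence_drop = 0.05) {
  presence <- features |>
    group_by(.data$subject_id, .data$map) |>
    summarise(present = any(.data$present), .groups = "drop") |>
    group_by(.data$map) |>
    summarise(absent_frac = mean(!.data$present), .groups = "drop")
  dropped <- presence$map[presence$absent_frac > absence_drop]
  kept <- features |> filter(!.data$map %in% dropped)
  wide <- kept |>
    mutate(mean_gfp = ifelse(is.na(.data$mean_gfp), 0, .data$mean_gfp)) |>
    tidyr::pivot_wider(
      id_cols = "subject_id",
      names_from = c("condition", "map"),
      values_from = c("duration_ms", "mean_gfp"),
      names_glue = "{condition}_{map}_{ifelse(.value == 'duration_ms', 'duration', 'gfp')}")
  cov <- subjects |> select(all_of(c("subject_id", covariates)))
  if ("sex" %in% names(cov)) cov$sex <- as.numeric(cov$sex == "M")
  out <- cov |> inner_join(wide, by = "subject_id")
  feature_cols <- setdiff(names(out), "subject_id")
  outcomes <- intersect(c("asd_outcome", "vabs_socialization", "group"),
                        names(subjects))
  out <- out |>
    left_join(subjects |> select(all_of(c("subject_id", outcomes))),
              by = "subject_id")
  attr(out, "feature_cols") <- feature_cols
  attr(out, "dropped_maps") <- dropped
  out
}

# Resolve the feature columns of a table built by build_feature_table(),
# falling back to "everything numeric that is not an id or outcome".
feature_cols_of <- function(table, features = NULL) {
  f <- features %||% attr(table, "feature_cols")
  if (is.null(f)) {
    f <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                 c("asd_outcome", "vabs_socialization"))
  }
  missing <- setdiff(f, names(table))
  if (length(missing)) {
    abort(paste("feature columns not in table:", paste(missing, collapse = ", ")))
  }
  f
}
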