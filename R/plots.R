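# ggplot2 visualisations for the package's result types.

#' @export
autoplot.erp_waveform <- function(object, ...) {
  df <- tidy(object)
  g <- tibble(time_ms = erp_times(object),
              gfp = gfp_columns(object$data))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude,
                                   group = .data$channel_id)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = g,
                       ggplot2::aes(.data$time_ms, .data$gfp, group = NULL),
                       colour = "red", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time (ms)", y = "amplitude (µV)",
                  title = sprintf("ERP butterfly plot (red: GFP) — %s / %s",
                                  object$subject_id, object$condition)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_maps <- function(object, ...) {
  df <- tidy(object)
  df$channel_id <- factor(df$channel_id, levels = object$channel_ids)
  ggplot2::ggplot(df, ggplot2::aes(.data$channel_id, .data$map,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "channel", y = NULL, fill = "normalized\namplitude",
                  title = "Microstate map topographies (unit GFP)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a microstate sequence: GFP trace coloured by the winning map
#'
#' @param seg An `ms_segmentation` from [fit_templates()].
#' @return A ggplot.
#' @export
plot_segmentation <- function(seg) {
  df <- as_tibble(seg)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$gfp,
                                   fill = .data$map)) +
    ggplot2::geom_col(width = max(diff(df$time_ms))) +
    ggplot2::labs(x = "time (ms)", y = "GFP (µV)", fill = "microstate",
                  title = "Microstate sequence") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_segmentation <- function(object, ...) plot_segmentation(object)

#' @export
autoplot.classifier_report <- function(object, ...) {
  df <- object$metrics
  df$metric <- factor(toupper(df$metric), levels = toupper(df$metric))
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.2) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = "Holdout classification performance",
                  subtitle = "bars: mean over repetitions; whiskers: averaged 95% CI") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.regression_report <- function(object, only_selected = TRUE, ...) {
  df <- object$coefficients
  if (only_selected) df <- df |> filter(.data$always_selected)
  df <- df |> arrange(.data$mean_coef) |>
    mutate(feature = factor(.data$feature, levels = .data$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_coef, .data$feature)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$mean_coef - .data$sd_coef,
      xmax = .data$mean_coef + .data$sd_coef), height = 0.2) +
    ggplot2::labs(x = "coefficient (standard units)", y = NULL,
                  title = "Elastic-net coefficients across outer folds",
                  subtitle = if (only_selected) "always-selected features only" else NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_model <- function(object, ...) {
  ggplot2::ggplot(object$ev, ggplot2::aes(.data$k, .data$mean_test_ev)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_opt, linetype = "dashed") +
    ggplot2::labs(x = "number of maps",
                  y = "held-out explained variance",
                  title = sprintf("Map-count selection (k_opt = %d)",
                                  object$k_opt)) +
    ggplot2::theme_minimal()
}
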