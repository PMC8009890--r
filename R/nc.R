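# Classic Nc event-related-potential features: frontal-region averaging,
# mean amplitude and peak latency in the Nc window, condition differences.

#' Montage: channel-to-region mapping
#'
#' A montage is a tibble mapping channel ids to scalp-region labels; the
#' Nc analysis needs at least the three frontal regions `frontal-left`,
#' `frontal-central` and `frontal-right` (other channels may map to
#' `"other"`). Regions must be disjoint and non-empty.
#'
#' @param channel_id Character vector of channel labels.
#' @param region Character vector of region labels, same length.
#' @return A `montage` tibble.
#' @export
montage <- function(channel_id, region) {
  if (anyDuplicated(channel_id)) {
    abort("montage regions must be disjoint: duplicated channel ids found")
  }
  out <- tibble(channel_id = as.character(channel_id),
                region = as.character(region))
  class(out) <- c("montage", class(out))
  out
}

#' Default frontal montage for the synthetic geodesic-style layouts
#'
#' Ships frontal-left/central/right channel sets for the 64- and
#' 128-channel synthetic layouts used by the simulator (channels
#' `E1..En`). These assignments are synthetic placeholders: real sensor
#' nets require a net-specific montage supplied by the user (the region
#' membership of a physical net is configuration, not code).
#'
#' @param n_channels 64 or 128.
#' @return A [montage()] covering the frontal regions, remaining channels
#'   mapped to `"other"`.
#' @export
default_montage <- function(n_channels = 64) {
  sets <- if (n_channels == 64) {
    list("frontal-left" = c(1, 2, 5, 6), "frontal-central" = c(3, 4, 7, 8),
         "frontal-right" = c(9, 10, 11, 12))
  } else if (n_channels == 128) {
    list("frontal-left" = c(1:4, 9:12), "frontal-central" = c(5:8, 13:16),
         "frontal-right" = c(17:20, 25:28))
  } else {
    abort("default montages exist for 64 and 128 channels only; supply your own")
  }
  ch <- sprintf("E%d", seq_len(n_channels))
  region <- rep("other", n_channels)
  for (r in names(sets)) region[sets[[r]]] <- r
  montage(ch, region)
}

#' Average a waveform over the channels of one region
#'
#' Unweighted mean across the region's channels at every time sample,
#' computed on average-referenced data for consistency with the
#' topographic analyses.
#'
#' @param erp An [erp_waveform()].
#' @param mont A [montage()].
#' @param region Region label present in the montage.
#' @return A tibble with `time_ms` and `amplitude` (microvolts).
#' @export
region_mean <- function(erp, mont, region) {
  chans <- mont$channel_id[mont$region == region]
  if (!length(chans)) abort(sprintf("unknown region '%s'", region))
  chans <- intersect(chans, erp$channel_ids)
  if (!length(chans)) {
    abort(sprintf("region '%s' has no channels in this recording", region))
  }
  erp <- average_reference(erp)
  tibble(time_ms = erp_times(erp),
         amplitude = colMeans(erp$data[chans, , drop = FALSE]))
}

#' Nc mean amplitude of a region-averaged waveform
#'
#' Mean amplitude over all samples whose time lies inside the window
#' (inclusive bounds). A window extending beyond the epoch — e.g. the
#' conventional 300-800 ms Nc window against an epoch ending at 794 ms —
#' is clipped to the epoch with a message.
#'
#' @param wave Tibble with `time_ms` and `amplitude`, as from
#'   [region_mean()].
#' @param window Window in ms, default `c(300, 800)`.
#' @return Mean amplitude in microvolts.
#' @export
nc_mean_amplitude <- function(wave, window = c(300, 800)) {
  window <- clip_window(window, wave$time_ms, "Nc window")
  idx <- window_index(wave$time_ms, window)
  if (!length(idx)) abort("Nc window contains no samples")
  mean(wave$amplitude[idx])
}

#' Nc peak latency of a region-averaged waveform
#'
#' Time of the most negative sample inside the window; ties are broken by
#' the earliest time. Window handling as in [nc_mean_amplitude()].
#'
#' @inheritParams nc_mean_amplitude
#' @return Latency in ms after stimulus onset.
#' @export
nc_peak_latency <- function(wave, window = c(300, 800)) {
  window <- clip_window(window, wave$time_ms, "Nc window")
  idx <- window_index(wave$time_ms, window)
  if (!length(idx)) abort("Nc window contains no samples")
  wave$time_ms[idx][which.min(wave$amplitude[idx])]
}

#' Condition difference score
#'
#' `feat_a - feat_b`, e.g. FD minus Noise for Nc amplitude or latency.
#'
#' @param feat_a,feat_b Scalar features from the same subject, region
#'   aggregation and window.
#' @return The difference.
#' @export
difference_score <- function(feat_a, feat_b) feat_a - feat_b

#' Nc features for a cohort of ERPs
#'
#' Computes, per subject, condition and frontal region (plus the overall
#' frontal average, the unweighted mean of the three region waveforms),
#' the Nc mean amplitude and peak latency.
#'
#' @param erps Tibble with `subject_id`, `condition` and an `erp`
#'   list-column (e.g. the `erps` element of a simulated cohort), or a
#'   list of [erp_waveform()] objects.
#' @param mont A [montage()]; defaults to the synthetic layout montage
#'   matching the first ERP's channel count.
#' @param window Nc window in ms.
#' @param regions Frontal region labels to analyse.
#' @return A tibble: `subject_id`, `condition`, `region`,
#'   `mean_amplitude`, `peak_latency`.
#' @export
nc_features <- function(erps, mont = NULL, window = c(300, 800),
                        regions = c("frontal-left", "frontal-central",
                                    "frontal-right")) {
  lst <- as_erp_list(erps)
  mont <- mont %||% default_montage(nrow(lst[[1L]]$data))
  rows <- map(lst, function(e) {
    waves <- map(regions, ~region_mean(e, mont, .x))
    frontal <- tibble(time_ms = waves[[1L]]$time_ms,
                      amplitude = rowMeans(
                        vapply(waves, function(w) w$amplitude,
                               numeric(nrow(waves[[1L]])))))
    waves <- c(waves, list(frontal))
    tibble(subject_id = e$subject_id, condition = e$condition,
           region = c(regions, "frontal"),
           mean_amplitude = map_dbl(waves, nc_mean_amplitude, window = window),
           peak_latency = map_dbl(waves, nc_peak_latency, window = window))
  })
  bind_rows(rows)
}

#' Nc difference scores between face conditions and Noise
#'
#' @param nc Tibble from [nc_features()].
#' @return Tibble with `subject_id`, `region`, `contrast`
#'   (`"FD-Noise"`, `"FA-Noise"`), `mean_amplitude_diff`,
#'   `peak_latency_diff`.
#' @export
nc_difference_scores <- function(nc) {
  wide <- nc |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("mean_amplitude", "peak_latency"))
  out <- list()
  for (cond in intersect(c("FD", "FA"), unique(nc$condition))) {
    out[[cond]] <- wide |>
      transmute(
        .data$subject_id, .data$region,
        contrast = paste0(cond, "-Noise"),
        mean_amplitude_diff = difference_score(
          .data[[paste0("mean_amplitude_", cond)]],
          .data$mean_amplitude_Noise),
        peak_latency_diff = difference_score(
          .data[[paste0("peak_latency_", cond)]],
          .data$peak_latency_Noise))
  }
  bind_rows(out)
}
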