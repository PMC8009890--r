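#' Construct an ERP waveform object
#'
#' An `erp_waveform` holds one subject-by-condition trial-averaged ERP: a
#' channel-by-sample matrix in microvolts together with its sampling
#' metadata. All analysis windows in the package are expressed in
#' milliseconds relative to stimulus onset; the first sample sits at
#' `t0_offset` ms and successive samples are `1000/fs` ms apart.
#'
#' @param data Numeric matrix, channels in rows, time samples in columns.
#' @param fs Sampling rate in Hz.
#' @param t0_offset Time of the first sample relative to stimulus onset, ms
#'   (negative for a pre-stimulus baseline).
#' @param channel_ids Character vector of channel labels, one per row.
#' @param condition Stimulus condition label (e.g. `"FD"`, `"FA"`,
#'   `"Noise"`).
#' @param subject_id Subject identifier.
#' @param reference Reference scheme of the recording, `"average"` or
#'   `"other"`.
#'
#' @return An object of class `erp_waveform`.
#' @export
erp_waveform <- function(data, fs, t0_offset, channel_ids = NULL,
                         condition = NA_character_,
                         subject_id = NA_character_,
                         reference = c("other", "average")) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data)) {
    abort("ERP data must be a numeric matrix with no missing samples")
  }
  if (is.null(channel_ids)) {
    channel_ids <- rownames(data) %||% sprintf("E%d", seq_len(nrow(data)))
  }
  if (length(channel_ids) != nrow(data)) {
    abort("channel_ids must have one entry per data row")
  }
  reference <- match.arg(reference)
  rownames(data) <- channel_ids
  structure(
    list(data = data, fs = fs, t0_offset = t0_offset,
         channel_ids = channel_ids, condition = condition,
         subject_id = subject_id, reference = reference),
    class = "erp_waveform"
  )
}

#' @export
print.erp_waveform <- function(x, ...) {
  tms <- erp_times(x)
  cat(sprintf(
    "<erp_waveform> subject %s, condition %s: %d channels x %d samples, %g Hz, %g..%g ms, %s reference\n",
    x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs,
    min(tms), max(tms), x$reference))
  invisible(x)
}

#' Sample times of an ERP waveform
#'
#' @param erp An [erp_waveform()].
#' @return Numeric vector of sample times in ms relative to stimulus onset.
#' @export
erp_times <- function(erp) {
  sample_times(ncol(erp$data), erp$fs, erp$t0_offset)
}

#' Re-reference an ERP to the average reference
#'
#' Subtracts the across-channel mean from every time sample, so each sample
#' (column) sums to zero. Topographic analyses (GFP, spatial correlation,
#' microstates) assume average-referenced data. The operation is idempotent.
#'
#' @param erp An [erp_waveform()] with at least two channels.
#' @return The re-referenced `erp_waveform` with `reference = "average"`.
#' @export
average_reference <- function(erp) {
  if (nrow(erp$data) < 2L) {
    abort("average reference requires at least 2 channels")
  }
  erp$data <- sweep(erp$data, 2L, colMeans(erp$data))
  erp$reference <- "average"
  erp
}

#' Convert an ERP waveform to a tidy tibble
#'
#' @param x An [erp_waveform()].
#' @param ... Unused.
#' @return A tibble with one row per channel and time sample:
#'   `subject_id`, `condition`, `channel_id`, `time_ms`, `amplitude`.
#' @export
tidy.erp_waveform <- function(x, ...) {
  tms <- erp_times(x)
  tibble(
    subject_id = x$subject_id,
    condition = x$condition,
    channel_id = rep(x$channel_ids, times = ncol(x$data)),
    time_ms = rep(tms, each = nrow(x$data)),
    amplitude = as.vector(x$data)
  )
}
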