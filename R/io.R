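# File formats: CSV matrices with JSON sidecars for ERPs, JSON montages,
# delimited tables for maps, segmentations and features.

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write / read an ERP waveform (CSV matrix + JSON sidecar)
#'
#' The canonical exchange format: a headerless CSV with one row per
#' channel and one column per sample, and a JSON sidecar named like the
#' CSV (`.json`) holding `subject_id`, `condition`, `fs`, `t0_offset_ms`,
#' `channel_ids` and `reference`. Round-tripping reproduces the data to
#' within 1e-9 microvolts and the metadata exactly.
#'
#' @param erp An [erp_waveform()].
#' @param path CSV file path.
#' @return `write_erp` returns `path` invisibly; `read_erp` returns an
#'   [erp_waveform()].
#' @export
write_erp <- function(erp, path) {
  utils::write.table(format(erp$data, digits = 15, trim = TRUE,
                            scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(subject_id = erp$subject_id, condition = erp$condition,
               fs = erp$fs, t0_offset_ms = erp$t0_offset,
               channel_ids = erp$channel_ids, reference = erp$reference)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_erp
#' @export
read_erp <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  for (field in c("fs", "t0_offset_ms", "channel_ids")) {
    if (is.null(meta[[field]])) {
      abort(sprintf("ERP sidecar %s is missing required field '%s'",
                    sidecar_path(path), field))
    }
  }
  raw <- utils::read.table(path, sep = ",", header = FALSE,
                           colClasses = "numeric")
  m <- as.matrix(raw)
  if (anyNA(m)) abort(sprintf("non-numeric or missing cells in %s", path))
  if (nrow(m) != length(meta$channel_ids)) {
    abort(sprintf("%s has %d rows but the sidecar lists %d channels",
                  path, nrow(m), length(meta$channel_ids)))
  }
  erp_waveform(m, fs = as.numeric(meta$fs),
               t0_offset = as.numeric(meta$t0_offset_ms),
               channel_ids = meta$channel_ids,
               condition = meta$condition %||% NA_character_,
               subject_id = meta$subject_id %||% NA_character_,
               reference = meta$reference %||% "other")
}

#' Write / read a montage as JSON
#'
#' @param mont A [montage()].
#' @param path JSON file path.
#' @export
write_montage <- function(mont, path) {
  jsonlite::write_json(as.list(setNames(mont$region, mont$channel_id)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  montage(names(m), unname(unlist(m)))
}

#' Write / read microstate maps (CSV + JSON metadata)
#'
#' Maps are stored as a CSV with one row per map (columns = channels,
#' header = channel ids) plus a JSON metadata sidecar carrying the
#' provenance note (window, reference group, k, polarity mode).
#'
#' @param maps An [ms_maps()].
#' @param path CSV file path.
#' @export
write_maps <- function(maps, path) {
  df <- as.data.frame(maps$maps)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(c(list(k = maps$k), maps$source),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maps
#' @export
read_maps <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else list()
  ms_maps(as.matrix(df), channel_ids = names(df),
          source = meta[setdiff(names(meta), "k")])
}

#' Write a segmentation to CSV
#'
#' One row per sample: `time_ms`, `label`, `map`, `gfp`, `spatial_corr`.
#'
#' @param seg An `ms_segmentation` from [fit_templates()].
#' @param path CSV file path.
#' @export
write_segmentation <- function(seg, path) {
  utils::write.csv(as.data.frame(seg), path, row.names = FALSE)
  invisible(path)
}
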