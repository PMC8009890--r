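#' Global field power of a scalp topography
#'
#' GFP is the standard deviation of the potential across channels at one
#' time sample (population form, i.e. dividing by the channel count), a
#' reference-independent measure of the strength of the scalp field.
#'
#' @param sample Numeric vector of channel values (microvolts), length >= 2.
#' @return GFP in microvolts.
#' @export
gfp <- function(sample) {
  if (length(sample) < 2L) abort("GFP requires at least 2 channels")
  v <- sample - mean(sample)
  sqrt(mean(v^2))
}

# Column-wise GFP of a channel x sample matrix (internal, vectorized).
gfp_columns <- function(mat) {
  centred <- sweep(mat, 2L, colMeans(mat))
  sqrt(colMeans(centred^2))
}

#' Normalize a topography to zero mean and unit GFP
#'
#' Average-references the vector and divides by its GFP, yielding the
#' "shape" of the scalp field stripped of its strength. Microstate template
#' matching operates on such normalized topographies.
#'
#' @param sample Numeric channel vector with non-zero GFP.
#' @return Numeric vector with mean 0 and GFP 1.
#' @export
normalize_topography <- function(sample) {
  v <- sample - mean(sample)
  g <- sqrt(mean(v^2))
  if (g == 0) abort("flat topography: GFP is zero, cannot normalize")
  v / g
}

#' Spatial correlation between two scalp topographies
#'
#' Pearson correlation across channels, equal to the cosine similarity of
#' the average-referenced vectors. The value is polarity-sensitive (signed):
#' in evoked-potential microstate analysis a sign flip is a different brain
#' state, because polarity carries component identity.
#'
#' @param a,b Numeric channel vectors of equal length >= 2, neither flat.
#' @return Correlation in \[-1, 1\].
#' @export
spatial_correlation <- function(a, b) {
  if (length(a) != length(b)) abort("topographies must have equal channel counts")
  if (length(a) < 2L) abort("spatial correlation requires at least 2 channels")
  av <- a - mean(a)
  bv <- b - mean(b)
  ga <- sqrt(mean(av^2))
  gb <- sqrt(mean(bv^2))
  if (ga == 0 || gb == 0) abort("flat topography: spatial correlation undefined")
  mean(av * bv) / (ga * gb)
}

#' Construct a set of microstate maps
#'
#' @param maps Numeric matrix, one map per row (channels in columns). Rows
#'   are average-referenced and normalized to unit GFP on construction.
#' @param channel_ids Optional channel labels.
#' @param source Optional provenance note (free-form list: reference group,
#'   condition, window, ...).
#' @return An object of class `ms_maps`.
#' @export
ms_maps <- function(maps, channel_ids = NULL, source = list()) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 2L) abort("a microstate map set needs k >= 2 maps")
  maps <- t(apply(maps, 1L, normalize_topography))
  if (is.null(channel_ids)) {
    channel_ids <- colnames(maps) %||% sprintf("E%d", seq_len(ncol(maps)))
  }
  dimnames(maps) <- list(sprintf("M%d", seq_len(nrow(maps))), channel_ids)
  structure(list(maps = maps, k = nrow(maps), channel_ids = channel_ids,
                 source = source),
            class = "ms_maps")
}

#' @export
print.ms_maps <- function(x, ...) {
  cat(sprintf("<ms_maps> %d maps x %d channels (zero-mean, unit-GFP rows)\n",
              x$k, ncol(x$maps)))
  invisible(x)
}

#' @rdname ms_maps
#' @param x An `ms_maps` object.
#' @param ... Unused.
#' @export
tidy.ms_maps <- function(x, ...) {
  tibble(
    map = rep(rownames(x$maps), times = ncol(x$maps)),
    channel_id = rep(colnames(x$maps), each = nrow(x$maps)),
    value = as.vector(x$maps)
  )
}

# Signed correlation of unit-GFP zero-mean rows of X (n x ch) against each
# unit-GFP zero-mean map (k x ch): X %*% t(M) / ch.
corr_to_maps <- function(x_norm, maps) {
  x_norm %*% t(maps) / ncol(maps)
}

# --- AAHC ------------------------------------------------------------------

# One atomize-and-agglomerate pass from singleton clusters down to k_min,
# recording the centroid set at every k in `record_ks`. `x_norm` holds
# normalized sample topographies in rows; `w` their GFP weights (the
# quality measure is the GFP-weighted squared correlation, i.e. the GEV
# numerator). Returns list(k = list of centroid matrices, labels_at_k).
aahc_path <- function(x_norm, w, record_ks, ignore_polarity = FALSE) {
  n <- nrow(x_norm)
  ch <- ncol(x_norm)
  k_min <- min(record_ks)
  if (k_min < 2L) abort("AAHC requires k >= 2")
  if (n < max(record_ks)) abort("more clusters requested than samples available")

  labels <- seq_len(n)
  centroids <- x_norm                      # cluster id -> centroid row
  active <- rep(TRUE, n)
  contrib <- w^2                           # singleton: corr = 1 with itself
  signs <- rep(1, n)                       # member polarity (ignore_polarity mode)

  recompute_cluster <- function(cid) {
    members <- which(labels == cid)
    xm <- x_norm[members, , drop = FALSE]
    if (ignore_polarity) xm <- xm * signs[members]
    m <- colMeans(xm)
    g <- sqrt(mean((m - mean(m))^2))
    if (g == 0) {
      # Degenerate cancellation; fall back to the first member's topography.
      m <- xm[1L, ]
      g <- 1
    }
    centroids[cid, ] <<- (m - mean(m)) / g
    cc <- as.vector(x_norm[members, , drop = FALSE] %*% centroids[cid, ]) / ch
    if (ignore_polarity) {
      signs[members] <<- ifelse(cc < 0, -1, 1)
      cc <- abs(cc)
    }
    contrib[cid] <<- sum((w[members] * cc)^2)
  }

  out <- vector("list", length(record_ks))
  names(out) <- as.character(record_ks)
  labels_at <- vector("list", length(record_ks))
  names(labels_at) <- as.character(record_ks)

  snapshot <- function(k_now) {
    pos <- match(as.character(k_now), names(out))
    if (!is.na(pos)) {
      ids <- which(active)
      # Order maps by total assigned contribution, descending; ties by id.
      ord <- ids[order(-contrib[ids], ids)]
      out[[pos]] <<- centroids[ord, , drop = FALSE]
      labels_at[[pos]] <<- match(labels, ord)
    }
  }

  k_now <- n
  snapshot(k_now)
  while (k_now > k_min) {
    ids <- which(active)
    worst <- ids[which.min(contrib[ids])]   # ties -> lowest cluster id
    members <- which(labels == worst)
    active[worst] <- FALSE
    contrib[worst] <- Inf
    ids <- which(active)
    cc <- x_norm[members, , drop = FALSE] %*% t(centroids[ids, , drop = FALSE]) / ch
    if (ignore_polarity) cc <- abs(cc)
    best <- ids[max.col(cc, ties.method = "first")]
    labels[members] <- best
    for (cid in unique(best)) recompute_cluster(cid)
    k_now <- k_now - 1L
    snapshot(k_now)
  }
  list(maps = out, labels = labels_at)
}

#' Atomize-and-agglomerate hierarchical clustering of topographies
#'
#' AAHC clusters scalp topographies bottom-up: every sample starts as its
#' own cluster; at each step the cluster contributing least to the global
#' explained variance (GEV) is dissolved ("atomized") and its members are
#' reassigned to the remaining cluster whose centroid they correlate with
#' best. Centroids are the polarity-aligned mean of members, renormalized
#' to zero mean and unit GFP. Clustering stops at `k_target` clusters;
#' centroids are returned ordered by total assigned GEV, descending.
#'
#' Correlations are signed by default (evoked-potential convention); set
#' `ignore_polarity = TRUE` for the resting-state convention where a map
#' and its sign flip are the same state.
#'
#' @param samples Numeric matrix of topographies, one sample per row.
#'   Rows are normalized internally; flat rows are rejected.
#' @param k_target Number of clusters to return (>= 2).
#' @param gfp_weights Optional per-sample GFP weights for the quality
#'   measure; defaults to the GFP of each input row (1 for pre-normalized
#'   input).
#' @param ignore_polarity Cluster on absolute correlations?
#' @return An [ms_maps()] object with an `assignment` attribute giving the
#'   winning map index per input sample.
#' @export
aahc_cluster <- function(samples, k_target, gfp_weights = NULL,
                         ignore_polarity = FALSE) {
  samples <- as.matrix(samples)
  g <- apply(samples, 1L, function(r) sqrt(mean((r - mean(r))^2)))
  if (any(g == 0)) abort("flat (zero-GFP) samples cannot be clustered")
  if (k_target < 2L || k_target > nrow(samples)) {
    abort("k_target must lie between 2 and the number of samples")
  }
  x_norm <- sweep(samples, 1L, rowMeans(samples)) / g
  w <- gfp_weights %||% g
  path <- aahc_path(x_norm, w, record_ks = k_target,
                    ignore_polarity = ignore_polarity)
  m <- ms_maps(path$maps[[1L]], channel_ids = colnames(samples))
  attr(m, "assignment") <- path$labels[[1L]]
  m
}

# --- Template fitting ------------------------------------------------------

#' Fit microstate map templates to an individual ERP
#'
#' Labels every sample in `window` with the map whose (signed) spatial
#' correlation with the sample's normalized topography is highest. Ties go
#' to the lowest map index. Flat (zero-GFP) samples cannot be normalized;
#' they carry the previous sample's label forward (a flat first sample
#' takes the label of the first non-flat sample), so that total durations
#' still conserve the window.
#'
#' @param erp An [erp_waveform()]; channel ids must match the maps.
#' @param maps An [ms_maps()] template set.
#' @param window Analysis window in ms (inclusive bounds), clipped to the
#'   epoch if needed.
#' @param ignore_polarity Match on absolute correlation?
#' @return An `ms_segmentation`: a tibble with one row per in-window sample
#'   (`time_ms`, `label`, `map`, `gfp`, `spatial_corr`) and attributes
#'   `window`, `k`, `fs`.
#' @export
fit_templates <- function(erp, maps, window = c(0, 794),
                          ignore_polarity = FALSE) {
  if (!identical(unname(erp$channel_ids), unname(maps$channel_ids))) {
    abort("channel ids of the ERP and the maps do not align")
  }
  tms <- erp_times(erp)
  window <- clip_window(window, tms, "fitting window")
  idx <- window_index(tms, window)
  x <- t(erp$data[, idx, drop = FALSE])          # samples x channels
  g <- gfp_columns(erp$data[, idx, drop = FALSE])
  labels <- integer(length(idx))
  corrs <- numeric(length(idx))
  ok <- g > 0
  if (any(ok)) {
    xn <- sweep(x[ok, , drop = FALSE], 1L, rowMeans(x[ok, , drop = FALSE])) / g[ok]
    cc <- corr_to_maps(xn, maps$maps)
    if (ignore_polarity) cc <- abs(cc)
    # max.col with ties.method = "first" gives the lowest map index on ties.
    win <- max.col(cc, ties.method = "first")
    labels[ok] <- win
    corrs[ok] <- cc[cbind(seq_len(sum(ok)), win)]
  }
  if (any(!ok)) {
    if (!any(ok)) abort("all samples in the window are flat; cannot segment")
    first_ok <- which(ok)[1L]
    labels[seq_len(first_ok - 1L)] <- labels[first_ok]
    corrs[seq_len(first_ok - 1L)] <- NA_real_
    for (i in which(!ok)) {
      if (i > first_ok) {
        labels[i] <- labels[i - 1L]
        corrs[i] <- NA_real_
      }
    }
  }
  seg <- tibble(
    time_ms = tms[idx],
    label = labels,
    map = rownames(maps$maps)[labels],
    gfp = unname(g),
    spatial_corr = corrs
  )
  attr(seg, "window") <- window
  attr(seg, "k") <- maps$k
  attr(seg, "fs") <- erp$fs
  class(seg) <- c("ms_segmentation", class(seg))
  seg
}

#' Per-map duration and mean GFP features from a segmentation
#'
#' Duration of map m is the total time labelled m inside the feature
#' window — the number of in-window samples times the sampling period —
#' counting non-contiguous occupancy, so durations always sum exactly to
#' the window length. Mean GFP is the mean of the raw (un-normalized) GFP
#' over those samples; a map with zero duration has `mean_gfp = NA` and
#' `present = FALSE`.
#'
#' @param seg An `ms_segmentation` from [fit_templates()].
#' @param k Number of maps in the template set (defaults to the
#'   segmentation's `k` attribute).
#' @param feature_window Window in ms over which features are taken
#'   (inclusive bounds); must lie within the segmentation window.
#' @param fs Sampling rate in Hz (defaults to the segmentation's `fs`).
#' @return A tibble with one row per map: `map`, `label`, `duration_ms`,
#'   `mean_gfp`, `present`.
#' @export
extract_features <- function(seg, k = attr(seg, "k"),
                             feature_window = c(300, 794),
                             fs = attr(seg, "fs")) {
  idx <- window_index(seg$time_ms, feature_window)
  if (length(idx) == 0L) abort("feature window contains no samples")
  dt <- 1000 / fs
  lab <- seg$label[idx]
  g <- seg$gfp[idx]
  counts <- tabulate(lab, nbins = k)
  mean_g <- vapply(seq_len(k), function(m) {
    if (counts[m] == 0L) NA_real_ else mean(g[lab == m])
  }, numeric(1))
  tibble(
    map = sprintf("M%d", seq_len(k)),
    label = seq_len(k),
    duration_ms = counts * dt,
    mean_gfp = mean_g,
    present = counts > 0L
  )
}

#' Global explained variance of an ERP under a map set
#'
#' GEV is the GFP-weighted squared spatial correlation between each sample
#' and its winning map, summed over the window and normalized by the summed
#' squared GFP: `sum((gfp_t * corr_t)^2) / sum(gfp_t^2)`. Lies in \[0, 1\];
#' equals 1 when every sample is an exact scaled copy of some map.
#'
#' @inheritParams fit_templates
#' @return GEV fraction in \[0, 1\].
#' @export
explained_variance <- function(erp, maps, window = c(0, 794),
                               ignore_polarity = FALSE) {
  seg <- fit_templates(erp, maps, window, ignore_polarity = ignore_polarity)
  den <- sum(seg$gfp^2)
  if (den == 0) abort("all samples flat: explained variance undefined")
  cc <- ifelse(is.na(seg$spatial_corr), 0, seg$spatial_corr)
  sum((seg$gfp * cc)^2) / den
}
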