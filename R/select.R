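# Cross-validated selection of the number of microstate maps.

# Coerce the accepted ERP inputs (list of erp_waveform, or a tibble with an
# `erp` list-column such as the `erps` element of a simulated cohort) to a
# plain list of erp_waveform objects.
as_erp_list <- function(erps) {
  if (is.data.frame(erps)) {
    if (!"erp" %in% names(erps)) abort("expected an `erp` list-column")
    erps <- erps$erp
  }
  if (inherits(erps, "erp_waveform")) erps <- list(erps)
  if (!length(erps) || !all(map_lgl(erps, inherits, "erp_waveform"))) {
    abort("expected erp_waveform objects")
  }
  erps
}

# Grand average of a list of ERPs sharing dimensions (unweighted mean).
grand_average_matrix <- function(erps) {
  Reduce(`+`, map(erps, "data")) / length(erps)
}

# Normalized in-window sample topographies and their GFPs for one ERP
# data matrix. Flat samples are dropped (they carry no topography).
window_topographies <- function(mat, tms, window) {
  idx <- window_index(tms, window)
  x <- t(mat[, idx, drop = FALSE])
  g <- gfp_columns(mat[, idx, drop = FALSE])
  ok <- g > 0
  list(xn = sweep(x[ok, , drop = FALSE], 1L,
                  rowMeans(x[ok, , drop = FALSE])) / g[ok],
       g = g[ok])
}

# GEV of topographies with per-sample winning correlation `win`.
gev_from_win <- function(g, win) sum((g * win)^2) / sum(g^2)

# Weighted closest-pair agglomeration of subject-level maps: repeatedly
# merge the two centroids with the highest spatial correlation until k
# clusters remain, recording the centroid set at every k in `record_ks`.
# Near-duplicate maps (the same state estimated in many subjects) collapse
# first, so weak but distinct states survive to small k. Weights are
# root-sum-square combined; centroids are weight-combined and renormalized.
merge_maps_path <- function(maps, w, record_ks, ignore_polarity = FALSE) {
  n <- nrow(maps)
  ch <- ncol(maps)
  k_min <- min(record_ks)
  if (n < k_min) abort("fewer maps than clusters requested")
  cc <- maps %*% t(maps) / ch
  diag(cc) <- -Inf
  sim <- if (ignore_polarity) abs(cc) else cc
  active <- rep(TRUE, n)
  out <- vector("list", length(record_ks))
  names(out) <- as.character(record_ks)
  snapshot <- function(k_now) {
    pos <- match(as.character(k_now), names(out))
    if (!is.na(pos)) {
      ids <- which(active)
      ord <- ids[order(-w[ids], ids)]
      out[[pos]] <<- maps[ord, , drop = FALSE]
    }
  }
  k_now <- n
  snapshot(k_now)
  while (k_now > k_min) {
    ij <- which(sim == max(sim[active, active]), arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    mj <- maps[j, ]
    if (ignore_polarity && cc[i, j] < 0) mj <- -mj
    v <- w[i] * maps[i, ] + w[j] * mj
    g <- sqrt(mean((v - mean(v))^2))
    maps[i, ] <- if (g == 0) maps[i, ] else (v - mean(v)) / g
    w[i] <- sqrt(w[i]^2 + w[j]^2)
    active[j] <- FALSE
    sim[j, ] <- -Inf; sim[, j] <- -Inf
    new_cc <- maps[active, , drop = FALSE] %*% maps[i, ] / ch
    cc[active, i] <- new_cc; cc[i, active] <- new_cc
    s <- if (ignore_polarity) abs(new_cc) else new_cc
    sim[active, i] <- s; sim[i, active] <- s
    sim[i, i] <- -Inf
    k_now <- k_now - 1L
    snapshot(k_now)
  }
  out
}

# Indices of (non-strict) local maxima of a GFP series. Map learning uses
# GFP-peak topographies: at GFP peaks the scalp field is most stable,
# whereas samples near segment transitions — where subjects' grand-averaged
# topographies blend and GFP dips through cancellation — are excluded, so
# the clusters represent stable states rather than transition mixtures.
gfp_peak_index <- function(g) {
  n <- length(g)
  if (n <= 2L) return(seq_len(n))
  up <- c(TRUE, g[-1L] >= g[-n])
  down <- c(g[-n] >= g[-1L], TRUE)
  which(up & down)
}

# Row maxima of a matrix (winning correlation per sample).
row_max <- function(m) do.call(pmax, as.data.frame(m))

#' Select the number of microstate maps by cross-validation
#'
#' Learns candidate map sets of every size in `k_range` in two stages —
#' AAHC on each subject's GFP-peak topographies, then weighted
#' closest-pair agglomeration of the pooled subject-level maps of the
#' training subjects — and scores each size by the mean global explained
#' variance (GEV) it achieves on held-out subjects' full ERPs. The
#' optimal k is the largest one whose held-out GEV significantly exceeds
#' that of k - 1 under a randomization test: the marginal gain of the
#' k-set's most novel map over the (k-1)-set is compared with the gain
#' obtained when that candidate's component orthogonal to the span of the
#' accepted maps is channel-permuted (same GFP and reference, destroyed
#' new topography), so only gains beyond already-modelled structure and
#' generic degrees-of-freedom inflation count. A candidate nearly
#' collinear with an accepted map is a refined duplicate of an existing
#' state, not a new one (see `duplicate_corr`). If no size beats its
#' predecessor, the smallest k in `k_range` is returned with a warning.
#' The returned maps are refit on all reference subjects at the selected
#' k. The methods vignette discusses why maps are learned from
#' subject-level GFP peaks rather than from the grand average.
#'
#' @param erps Reference-group ERPs: a list of [erp_waveform()] objects or
#'   a tibble with an `erp` list-column (e.g. the FD condition of the
#'   reference group).
#' @param k_range Contiguous ascending candidate map counts (default 2:7).
#' @param window Clustering window in ms (default 0-794, post-stimulus).
#' @param n_splits Number of random train/test splits (default 10).
#' @param train_fraction Fraction of subjects used for map learning per
#'   split (default 0.5).
#' @param n_rand Randomizations for the gain test (default 200).
#' @param alpha Significance level for the gain test (default 0.05).
#' @param peaks_only Learn maps from GFP-peak topographies of the grand
#'   average only (default). Peaks carry the most stable fields; samples
#'   near segment transitions, where grand-averaged topographies blend
#'   across subjects and GFP dips, are excluded so that clusters represent
#'   stable states rather than transition mixtures. Held-out explained
#'   variance is still computed over all window samples.
#' @param duplicate_corr A step-k candidate map whose |spatial correlation|
#'   with the nearest accepted map reaches this bound (default 0.9) in the
#'   majority of splits is a refined duplicate of an existing state, not a
#'   new one; the step is then judged non-significant.
#' @param ignore_polarity Cluster/fit on absolute correlations?
#' @param seed Integer seed; fully determines splits and randomizations.
#' @return An object of class `ms_model`: list with `k_opt`, `maps` (an
#'   [ms_maps()]), `ev` (tibble of per-k mean held-out GEV, gain and
#'   randomization p), and the call parameters.
#' @export
select_n_maps <- function(erps, k_range = 2:7, window = c(0, 794),
                          n_splits = 10, train_fraction = 0.5,
                          n_rand = 200, alpha = 0.05,
                          peaks_only = TRUE, duplicate_corr = 0.9,
                          ignore_polarity = FALSE, seed = NULL) {
  erps <- as_erp_list(erps)
  n_sub <- length(erps)
  if (n_sub < 4L) abort("need at least 4 reference subjects")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L) abort("k_range must start at >= 2")
  if (length(k_range) > 1L && any(diff(k_range) != 1L)) {
    abort("k_range must be contiguous")
  }
  tms <- erp_times(erps[[1L]])
  window <- clip_window(window, tms, "clustering window")
  ks <- k_range
  kcs <- as.character(ks)

  seeds <- child_seeds(seed %||% sample.int(2^30, 1L), n_splits + 1L)

  # Stage 1 (per subject): cluster each subject's GFP-peak topographies
  # into max(k_range) subject-level maps. Individual ERPs switch between
  # states sharply, so subject-level peak topographies are pure states;
  # learning from them avoids the transition mixtures that contaminate a
  # grand average when subjects' segment boundaries differ.
  subject_tw <- map(erps, ~window_topographies(.x$data, tms, window))
  k_max <- max(ks)
  subject_maps <- map(subject_tw, function(tw) {
    pk <- if (peaks_only) gfp_peak_index(tw$g) else seq_along(tw$g)
    if (length(pk) < k_max) pk <- seq_along(tw$g)
    pa <- aahc_path(tw$xn[pk, , drop = FALSE], tw$g[pk],
                    record_ks = k_max, ignore_polarity = ignore_polarity)
    m <- pa$maps[[1L]]
    lab <- pa$labels[[1L]]
    g <- tw$g[pk]
    # weight: root total GFP-weighted squared fit of the cluster (µV scale)
    w <- vapply(seq_len(nrow(m)), function(cl) {
      mem <- lab == cl
      cc <- tw$xn[pk, , drop = FALSE][mem, , drop = FALSE] %*% m[cl, ] /
        ncol(m)
      sqrt(sum((g[mem] * cc)^2))
    }, numeric(1))
    list(maps = m, w = w)
  })

  # Stage 2 (per split): pool the training subjects' maps and cluster the
  # pooled set down through k_range; score every k on held-out subjects.
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    splits[[s]] <- with_seed(seeds[s], {
      n_train <- max(1L, min(n_sub - 1L, round(train_fraction * n_sub)))
      train <- sort(sample.int(n_sub, n_train))
      test <- setdiff(seq_len(n_sub), train)
      pooled <- do.call(rbind, map(subject_maps[train], "maps"))
      pw <- unlist(map(subject_maps[train], "w"))
      path_maps <- merge_maps_path(pooled, pw, record_ks = ks,
                                   ignore_polarity = ignore_polarity)
      test_tw <- subject_tw[test]
      win <- map(kcs, function(kc) {
        m <- path_maps[[kc]]
        map(test_tw, function(tt) {
          cc <- tt$xn %*% t(m) / ncol(m)
          if (ignore_polarity) cc <- abs(cc)
          row_max(cc)
        })
      })
      names(win) <- kcs
      list(maps = path_maps[kcs], test = test_tw, win = win)
    })
  }

  ev_split_subject <- function(kc) {
    unlist(map(splits, function(sp) {
      mapply(function(tt, w) gev_from_win(tt$g, w), sp$test, sp$win[[kc]])
    }))
  }
  ev_k <- vapply(kcs, function(kc) mean(ev_split_subject(kc)), numeric(1))

  n_ch <- nrow(erps[[1L]]$data)
  perms <- with_seed(seeds[n_splits + 1L],
                     replicate(n_rand, sample.int(n_ch), simplify = FALSE))

  gain <- rep(NA_real_, length(ks))
  p_gain <- rep(NA_real_, length(ks))
  for (j in seq_along(ks)[-1L]) {
    km1 <- as.character(ks[j] - 1L)
    # Test statistic: the marginal held-out GEV gain of adding the map that
    # distinguishes the k-set from the (k-1)-set, holding the k-1 maps
    # fixed — the same construction the null uses, so the test is
    # calibrated (the full k-set's gain also contains centroid refinements
    # the null cannot express).
    obs_sum <- 0
    null_sum <- numeric(n_rand)
    n_terms <- 0L
    dup <- logical(0)
    for (s in seq_len(n_splits)) {
      sp <- splits[[s]]
      mk <- sp$maps[[as.character(ks[j])]]
      mk1 <- sp$maps[[km1]]
      if (is.null(mk) || is.null(mk1)) next
      # Candidate "new state" of step k: the map of the k-set least
      # explained by the (k-1)-set. A candidate nearly collinear with an
      # accepted map is a refined duplicate of an existing state, not a
      # new one.
      cors <- abs(mk %*% t(mk1) / n_ch)
      novelty <- apply(cors, 1L, max)
      d <- mk[which.min(novelty), ]
      dup <- c(dup, min(novelty) >= duplicate_corr)
      # Split the candidate map into its component inside the span of the
      # accepted k-1 maps and the orthogonal remainder, and permute only
      # the remainder: the null map mimics every way the candidate could
      # profit from already-modelled structure (plus generic
      # degrees-of-freedom inflation) while carrying no new topography.
      b <- qr.Q(qr(t(mk1)))
      d_par <- drop(b %*% crossprod(b, d))
      d_perp <- d - d_par
      p_maps <- vapply(perms, function(p) {
        v <- d_par + d_perp[p]
        g <- sqrt(mean((v - mean(v))^2))
        if (g == 0) d[p] else (v - mean(v)) / g
      }, numeric(n_ch))                                  # ch x n_rand
      for (i in seq_along(sp$test)) {
        tt <- sp$test[[i]]
        c0 <- sp$win[[km1]][[i]]
        cd <- drop(tt$xn %*% d / n_ch)
        cn <- tt$xn %*% p_maps / n_ch
        if (ignore_polarity) { cd <- abs(cd); cn <- abs(cn) }
        obs_sum <- obs_sum + gev_from_win(tt$g, pmax(c0, cd))
        w_aug <- pmax(cn, c0)               # recycles c0 down columns
        null_sum <- null_sum + colSums((tt$g * w_aug)^2) / sum(tt$g^2)
        n_terms <- n_terms + 1L
      }
    }
    gain[j] <- obs_sum / n_terms - ev_k[j - 1L]
    null_gain <- null_sum / n_terms - ev_k[j - 1L]
    p_gain[j] <- (1 + sum(null_gain >= gain[j])) / (n_rand + 1)
    # A candidate map nearly collinear with an already-accepted map is a
    # refined duplicate of an existing state, not a new one: the step does
    # not add a map regardless of its explained-variance gain.
    if (length(dup) && mean(dup) > 0.5) p_gain[j] <- 1
  }

  sig <- which(!is.na(p_gain) & p_gain < alpha)
  if (length(sig)) {
    k_opt <- ks[max(sig)]
  } else {
    k_opt <- ks[1L]
    warn(sprintf(
      "no map count in %d..%d significantly improved held-out explained variance; returning the floor k = %d",
      min(ks), max(ks), k_opt))
  }

  pooled_all <- do.call(rbind, map(subject_maps, "maps"))
  final_maps <- merge_maps_path(pooled_all, unlist(map(subject_maps, "w")),
                                record_ks = k_opt,
                                ignore_polarity = ignore_polarity)[[1L]]
  final <- ms_maps(final_maps)
  final$channel_ids <- erps[[1L]]$channel_ids
  colnames(final$maps) <- final$channel_ids
  final$source <- list(window = window, k = k_opt, n_subjects = n_sub,
                       polarity = if (ignore_polarity) "ignored" else "signed")

  structure(
    list(k_opt = k_opt, maps = final,
         ev = tibble(k = ks, mean_test_ev = unname(ev_k),
                     gain = gain, p_gain = p_gain),
         params = list(k_range = ks, window = window, n_splits = n_splits,
                       train_fraction = train_fraction, n_rand = n_rand,
                       alpha = alpha, ignore_polarity = ignore_polarity,
                       seed = seed)),
    class = "ms_model")
}

#' @export
print.ms_model <- function(x, ...) {
  cat(sprintf("<ms_model> optimal number of microstate maps: %d\n", x$k_opt))
  print(x$ev)
  invisible(x)
}

#' @rdname select_n_maps
#' @param x An `ms_model`.
#' @param ... Unused.
#' @export
tidy.ms_model <- function(x, ...) x$ev

#' @rdname select_n_maps
#' @export
glance.ms_model <- function(x, ...) {
  tibble(k_opt = x$k_opt,
         mean_test_ev = x$ev$mean_test_ev[match(x$k_opt, x$ev$k)],
         n_splits = x$params$n_splits,
         n_rand = x$params$n_rand)
}
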