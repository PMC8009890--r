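# Synthetic-cohort generator: multichannel ERPs with planted microstate
# structure and outcomes statistically linked to the planted features.

#' Default group-by-condition microstate segment plan
#'
#' Defines, for each outcome group and stimulus condition, the ordered
#' sequence of planted maps with their durations (ms) and mean GFP
#' (microvolts) over the post-stimulus epoch. The default emulates the
#' qualitative pattern reported for infants at elevated likelihood with a
#' later ASD diagnosis — shorter M1 and M4 and longer M2 to the face with
#' direct gaze, weaker M4 field strength to faces and a stronger one to
#' the control stimulus — on an M1-M2-M3-M4-M1 progression: the early
#' visual state recurs late in the epoch, so every map (except the
#' sometimes-absent M3) occupies part of the 300-794 ms feature window in
#' every subject, as the emulated feature design requires. Durations in
#' each row set sum to the post-stimulus window (796 ms of sample
#' occupancy at 500 Hz, samples at 0..794 ms).
#'
#' @return A tibble with columns `group`, `condition`, `segment`, `map`,
#'   `duration_ms`, `gfp`.
#' @export
default_segment_plan <- function() {
  plan <- rbind(
    c("noFH-noASD", "FD",    150, 2.2, 200, 2.6,  80, 1.8, 250, 3.2, 116, 2.0),
    c("FH-noASD",   "FD",    140, 2.2, 210, 2.6,  80, 1.8, 246, 3.0, 120, 2.0),
    c("FH-ASD",     "FD",    100, 2.0, 290, 2.6,  80, 1.8, 210, 2.6, 116, 2.0),
    c("noFH-noASD", "FA",    150, 2.1, 220, 2.4,  80, 1.6, 230, 2.9, 116, 2.0),
    c("FH-noASD",   "FA",    145, 2.1, 225, 2.4,  80, 1.6, 230, 2.8, 116, 2.0),
    c("FH-ASD",     "FA",    120, 2.0, 260, 2.4,  80, 1.6, 220, 2.6, 116, 2.0),
    c("noFH-noASD", "Noise", 180, 2.0, 260, 2.2,  80, 1.5, 160, 2.4, 116, 1.9),
    c("FH-noASD",   "Noise", 180, 2.0, 260, 2.2,  80, 1.5, 160, 2.5, 116, 1.9),
    c("FH-ASD",     "Noise", 170, 2.0, 270, 2.2,  80, 1.5, 160, 2.7, 116, 1.9)
  )
  out <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
    r <- plan[i, ]
    data.frame(group = r[1], condition = r[2], segment = 1:5,
               map = c(1L, 2L, 3L, 4L, 1L),
               duration_ms = as.numeric(r[c(3, 5, 7, 9, 11)]),
               gfp = as.numeric(r[c(4, 6, 8, 10, 12)]))
  }))
  as_tibble(out)
}

#' Simulation configuration for a synthetic ERP cohort
#'
#' Bundles every parameter of the generator. The defaults mirror the
#' emulated study design: three outcome groups of 40/72/19 subjects, three
#' stimulus conditions (face-direct FD, face-averted FA, Noise), 64
#' channels at 500 Hz over a -200..794 ms epoch, and four planted maps.
#' The continuous outcome (a socialization standard score) is a linear
#' function of planted microstate features plus a sex effect and Gaussian
#' noise; the binary outcome is group membership (FH-ASD).
#'
#' @param n_channels Number of channels (default 64; any value >= n_maps).
#' @param fs Sampling rate in Hz.
#' @param epoch Epoch window in ms, `c(start, end)`.
#' @param n_maps Number of planted topographies.
#' @param group_sizes Named counts per outcome group.
#' @param conditions Condition labels.
#' @param segment_plan Tibble as produced by [default_segment_plan()].
#' @param duration_jitter_sd SD (ms) of per-subject truncated-Gaussian
#'   duration jitter; segments are re-normalized to the window.
#' @param gfp_jitter_sd SD (microvolts) of per-subject segment-GFP jitter.
#' @param map_absence_prob Per-map probability that a subject lacks the map
#'   entirely (its time is redistributed over the other segments). The
#'   default makes map 3 absent in ~15% of subjects, so that the default
#'   machine-learning feature set retains maps 1, 2 and 4 only.
#' @param noise_sd SD (microvolts) of additive spatially white sensor noise
#'   on the averaged ERP.
#' @param outcome_betas Named coefficients linking planted features
#'   (names like `"FD_M4_duration"`, `"Noise_M4_gfp"`) to the continuous
#'   outcome.
#' @param outcome_intercept Continuous-outcome intercept.
#' @param sex_effect Additive effect on the continuous outcome for males.
#' @param outcome_noise_sd Residual SD of the continuous outcome.
#' @param male_prop Proportion of males.
#' @param trial_lambda Poisson mean of extra valid trials per condition on
#'   top of a floor of 10 (default cohorts therefore pass the inclusion
#'   rule; set `trial_floor` lower to simulate excluded subjects).
#' @param trial_floor Minimum simulated valid-trial count.
#' @param max_abs_corr Maximum pairwise |spatial correlation| between
#'   planted maps.
#' @param seed Integer seed; fully determines the cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_channels = 64, fs = 500, epoch = c(-200, 794),
                       n_maps = 4,
                       group_sizes = c("noFH-noASD" = 40, "FH-noASD" = 72,
                                       "FH-ASD" = 19),
                       conditions = c("FD", "FA", "Noise"),
                       segment_plan = default_segment_plan(),
                       duration_jitter_sd = 30, gfp_jitter_sd = 0.25,
                       map_absence_prob = c(0, 0, 0.15, 0),
                       noise_sd = 0.5,
                       outcome_betas = c(FD_M4_duration = 0.06,
                                         FD_M4_gfp = 8,
                                         Noise_M4_gfp = -6),
                       outcome_intercept = 90,
                       sex_effect = -6,
                       outcome_noise_sd = 8,
                       male_prop = 0.5,
                       trial_lambda = 15, trial_floor = 10,
                       max_abs_corr = 0.5,
                       seed = 1) {
  stopifnot(all(group_sizes > 0), n_maps >= 2, n_channels >= n_maps)
  n_samples <- (epoch[2] - epoch[1]) * fs / 1000 + 1
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    abort("fs and epoch must yield an integer sample count")
  }
  post_len <- sum(sample_times(round(n_samples), fs, epoch[1]) >= 0) * 1000 / fs
  sums <- segment_plan |>
    group_by(.data$group, .data$condition) |>
    summarise(total = sum(.data$duration_ms), .groups = "drop")
  if (any(abs(sums$total - post_len) > 1e-6)) {
    abort(sprintf(
      "segment durations must sum to the post-stimulus occupancy (%g ms) in every group x condition",
      post_len))
  }
  if (length(map_absence_prob) != n_maps) {
    map_absence_prob <- rep_len(map_absence_prob, n_maps)
  }
  structure(
    list(n_channels = n_channels, fs = fs, epoch = epoch, n_maps = n_maps,
         group_sizes = group_sizes, conditions = conditions,
         segment_plan = segment_plan,
         duration_jitter_sd = duration_jitter_sd,
         gfp_jitter_sd = gfp_jitter_sd,
         map_absence_prob = map_absence_prob, noise_sd = noise_sd,
         outcome_betas = outcome_betas,
         outcome_intercept = outcome_intercept, sex_effect = sex_effect,
         outcome_noise_sd = outcome_noise_sd, male_prop = male_prop,
         trial_lambda = trial_lambda, trial_floor = trial_floor,
         max_abs_corr = max_abs_corr, seed = seed),
    class = "sim_config")
}

#' Generate random planted microstate maps
#'
#' Draws `n_maps` average-referenced, unit-GFP topographies whose pairwise
#' |spatial correlation| does not exceed `max_abs_corr`, by rejection
#' sampling. With only 2 channels the average reference leaves a single
#' degree of freedom, so any two maps are exactly anti-correlated; that
#' degenerate pair is accepted (in polarity-sensitive analysis a sign flip
#' is a distinct state).
#'
#' @param n_maps Number of maps (>= 2).
#' @param n_channels Number of channels (>= n_maps).
#' @param max_abs_corr Pairwise correlation bound, in (0, 1).
#' @param seed Integer seed.
#' @param max_tries Draws allowed per map before giving up.
#' @return An [ms_maps()] object.
#' @export
make_maps <- function(n_maps, n_channels, max_abs_corr = 0.5, seed = NULL,
                      max_tries = 2000) {
  stopifnot(n_maps >= 2, n_channels >= n_maps,
            max_abs_corr > 0, max_abs_corr < 1)
  with_seed(seed, {
    maps <- matrix(NA_real_, n_maps, n_channels)
    maps[1L, ] <- normalize_topography(rnorm(n_channels))
    for (i in seq_len(n_maps)[-1L]) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- normalize_topography(rnorm(n_channels))
        cc <- maps[seq_len(i - 1L), , drop = FALSE] %*% cand / n_channels
        if (n_channels == 2L || all(abs(cc) <= max_abs_corr)) {
          maps[i, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "could not draw map %d with pairwise |correlation| <= %g in %d tries; relax max_abs_corr",
          i, max_abs_corr, max_tries))
      }
    }
    ms_maps(maps, channel_ids = sprintf("E%d", seq_len(n_channels)),
            source = list(kind = "planted", max_abs_corr = max_abs_corr))
  })
}

# Convert a per-subject plan (map, duration_ms, gfp) to per-sample planted
# labels and GFPs over the post-stimulus samples. Durations are snapped to
# the sample grid; rounding slack lands on the longest segment.
plan_to_samples <- function(plan, n_post, dt) {
  counts <- round(plan$duration_ms / dt)
  slack <- n_post - sum(counts)
  if (slack != 0L) {
    j <- which.max(counts)
    counts[j] <- counts[j] + slack
    if (counts[j] < 0L) abort("segment durations incompatible with the window")
  }
  list(label = rep(plan$map, counts), gfp = rep(plan$gfp, counts))
}

#' Simulate one averaged ERP from a planted segment plan
#'
#' Each planned segment contributes samples equal to its mean GFP times its
#' (unit-GFP) map topography; pre-stimulus samples are noise only. Additive
#' Gaussian sensor noise of SD `noise_sd` is applied per channel and
#' sample. Deterministic given `seed`.
#'
#' @param maps An [ms_maps()] set of planted topographies.
#' @param plan Data frame with columns `map` (index into `maps`),
#'   `duration_ms`, `gfp`; durations must sum to the post-stimulus sample
#'   occupancy.
#' @param noise_sd Sensor noise SD in microvolts.
#' @param fs Sampling rate in Hz.
#' @param epoch Epoch in ms.
#' @param seed Integer seed.
#' @param subject_id,condition Metadata carried on the waveform.
#' @return An [erp_waveform()] with attributes `planted_labels` and
#'   `planted_gfp` (per post-stimulus sample) for recovery testing.
#' @export
simulate_erp <- function(maps, plan, noise_sd = 0, fs = 500,
                         epoch = c(-200, 794), seed = NULL,
                         subject_id = NA_character_,
                         condition = NA_character_) {
  if (any(plan$duration_ms < 0) || any(plan$gfp < 0)) {
    abort("segment durations and GFPs must be non-negative")
  }
  if (any(plan$map < 1 | plan$map > maps$k)) abort("plan references unknown maps")
  n_ch <- ncol(maps$maps)
  dt <- 1000 / fs
  tms <- seq(epoch[1], epoch[2], by = dt)
  n_pre <- sum(tms < 0)
  n_post <- length(tms) - n_pre
  if (abs(sum(plan$duration_ms) - n_post * dt) > 1e-6) {
    abort(sprintf("plan durations must sum to the post-stimulus occupancy (%g ms)",
                  n_post * dt))
  }
  ps <- plan_to_samples(plan, n_post, dt)
  with_seed(seed, {
    clean <- cbind(matrix(0, n_ch, n_pre),
                   unname(t(maps$maps[ps$label, , drop = FALSE] * ps$gfp)))
    noise <- if (noise_sd > 0) {
      matrix(rnorm(n_ch * length(tms), sd = noise_sd), n_ch)
    } else 0
    erp <- erp_waveform(clean + noise, fs = fs, t0_offset = epoch[1],
                        channel_ids = colnames(maps$maps),
                        condition = condition, subject_id = subject_id,
                        reference = "average")
    attr(erp, "planted_labels") <- ps$label
    attr(erp, "planted_gfp") <- ps$gfp
    erp
  })
}

# Per-subject realization of a group plan: truncated-Gaussian duration
# jitter (renormalized to the window), Gaussian GFP jitter (floored), and
# optional whole-map absence with proportional redistribution.
realize_plan <- function(plan, absent, duration_jitter_sd, gfp_jitter_sd) {
  total <- sum(plan$duration_ms)
  d <- pmax(0, plan$duration_ms + rnorm(nrow(plan), 0, duration_jitter_sd))
  d[absent[plan$map]] <- 0
  if (sum(d) == 0) d[which.max(plan$duration_ms)] <- total
  d <- d / sum(d) * total
  g <- pmax(0.2, plan$gfp + rnorm(nrow(plan), 0, gfp_jitter_sd))
  tibble(map = plan$map, duration_ms = d, gfp = g)
}

#' Simulate a full cohort of subjects, ERPs and linked outcomes
#'
#' Generates the planted maps, one ERP per subject and condition following
#' the group-level segment plan with per-subject jitter, subject covariates
#' (sex, age, developmental level, valid-trial counts), and outcomes: the
#' binary outcome is membership of the third group; the continuous
#' socialization score is `intercept + sex_effect * male +
#' sum(outcome_betas * planted features) + N(0, outcome_noise_sd)`, where
#' planted features are the realized per-condition map durations and GFPs
#' inside `feature_window`.
#'
#' @param config A [sim_config()].
#' @param feature_window Window (ms) over which ground-truth features are
#'   computed (default 300-794, matching the microstate feature window).
#' @return An `erp_cohort` list with tibbles `subjects`, `erps` (one row
#'   per subject x condition with an `erp` list-column), `truth` (planted
#'   per-map features), plus the planted `maps` and the `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            feature_window = c(300, 794)) {
  cfg <- config
  seeds <- child_seeds(cfg$seed, 6L)
  maps <- make_maps(cfg$n_maps, cfg$n_channels, cfg$max_abs_corr,
                    seed = seeds[1L])
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  dt <- 1000 / cfg$fs

  subjects <- with_seed(seeds[2L], {
    tibble(
      subject_id = ids,
      group = factor(groups, levels = names(cfg$group_sizes)),
      sex = factor(ifelse(runif(n) < cfg$male_prop, "M", "F"),
                   levels = c("F", "M")),
      age_days = as.integer(round(rnorm(n, 250, 10))),
      msel_composite = round(rnorm(n, 100, 15), 1)
    )
  })
  trials <- with_seed(seeds[3L], {
    m <- matrix(cfg$trial_floor + rpois(n * length(cfg$conditions),
                                        cfg$trial_lambda), n)
    colnames(m) <- paste0("trials_", cfg$conditions)
    as_tibble(m)
  })
  subjects <- bind_cols(subjects, trials)

  absence <- with_seed(seeds[4L], {
    matrix(runif(n * cfg$n_maps) < rep(cfg$map_absence_prob, each = n), n)
  })

  erp_seeds <- child_seeds(seeds[5L], n * length(cfg$conditions))
  erps <- vector("list", n * length(cfg$conditions))
  truth <- vector("list", n * length(cfg$conditions))
  row <- 0L
  for (i in seq_len(n)) {
    for (cond in cfg$conditions) {
      row <- row + 1L
      plan0 <- cfg$segment_plan |>
        filter(.data$group == groups[i], .data$condition == cond) |>
        arrange(.data$segment)
      real <- with_seed(erp_seeds[row],
                        realize_plan(plan0, absence[i, ],
                                     cfg$duration_jitter_sd,
                                     cfg$gfp_jitter_sd))
      erp <- simulate_erp(maps, real, noise_sd = cfg$noise_sd, fs = cfg$fs,
                          epoch = cfg$epoch, seed = erp_seeds[row] + 1L,
                          subject_id = ids[i], condition = cond)
      erps[[row]] <- erp
      # Ground truth: realized per-sample labels/GFPs inside feature_window.
      tms_post <- seq(0, by = dt, length.out = length(attr(erp, "planted_labels")))
      inw <- tms_post >= feature_window[1] & tms_post <= feature_window[2]
      lab <- attr(erp, "planted_labels")[inw]
      gv <- attr(erp, "planted_gfp")[inw]
      counts <- tabulate(lab, nbins = cfg$n_maps)
      truth[[row]] <- tibble(
        subject_id = ids[i], condition = cond,
        map = sprintf("M%d", seq_len(cfg$n_maps)),
        duration_ms = counts * dt,
        mean_gfp = vapply(seq_len(cfg$n_maps), function(m) {
          if (counts[m] == 0L) NA_real_ else mean(gv[lab == m])
        }, numeric(1)),
        present = counts > 0L
      )
    }
  }
  erps_tbl <- tibble(
    subject_id = rep(ids, each = length(cfg$conditions)),
    condition = rep(cfg$conditions, times = n),
    erp = erps
  )
  truth_tbl <- bind_rows(truth)

  # Outcomes from planted features (wide names: <condition>_M<m>_<feature>).
  truth_wide <- truth_tbl |>
    mutate(mean_gfp = ifelse(is.na(.data$mean_gfp), 0, .data$mean_gfp)) |>
    tidyr::pivot_wider(
      id_cols = "subject_id",
      names_from = c("condition", "map"),
      values_from = c("duration_ms", "mean_gfp"),
      names_glue = "{condition}_{map}_{ifelse(.value == 'duration_ms', 'duration', 'gfp')}")
  stopifnot(identical(truth_wide$subject_id, ids))
  lin <- rep(cfg$outcome_intercept, n) +
    cfg$sex_effect * (subjects$sex == "M")
  for (nm in names(cfg$outcome_betas)) {
    if (!nm %in% names(truth_wide)) {
      abort(sprintf("outcome beta '%s' names no planted feature", nm))
    }
    lin <- lin + cfg$outcome_betas[[nm]] * truth_wide[[nm]]
  }
  subjects$vabs_socialization <- with_seed(seeds[6L],
    round(lin + rnorm(n, 0, cfg$outcome_noise_sd), 1))
  subjects$asd_outcome <- subjects$group == "FH-ASD"

  structure(list(subjects = subjects, erps = erps_tbl, truth = truth_tbl,
                 maps = maps, config = cfg),
            class = "erp_cohort")
}

#' @export
print.erp_cohort <- function(x, ...) {
  cat(sprintf("<erp_cohort> %d subjects (%s), %d ERPs, %d planted maps, %d channels\n",
              nrow(x$subjects),
              paste(table(x$subjects$group), collapse = "/"),
              nrow(x$erps), x$maps$k, x$config$n_channels))
  invisible(x)
}

#' Apply the minimal-trial inclusion rule
#'
#' Retains subjects providing at least `min_trials` valid trials in every
#' condition (inclusive bound). Rows with a missing trial count are
#' excluded with a reported reason. Order is preserved.
#'
#' @param subjects Subject tibble with per-condition `trials_*` columns.
#' @param min_trials Minimum valid trials per condition (default 10).
#' @param trial_cols Names of the trial-count columns (default: all columns
#'   starting with `trials_`).
#' @return The retained rows, with the excluded rows and their reasons
#'   available as `attr(., "excluded")`.
#' @export
apply_inclusion <- function(subjects, min_trials = 10,
                            trial_cols = grep("^trials_", names(subjects),
                                              value = TRUE)) {
  if (!length(trial_cols)) abort("no trial-count columns found")
  m <- as.matrix(subjects[, trial_cols])
  reason <- rep(NA_character_, nrow(subjects))
  has_na <- apply(m, 1L, anyNA)
  reason[has_na] <- "missing trial count"
  below <- !has_na & apply(m, 1L, function(r) any(r < min_trials))
  reason[below] <- sprintf("fewer than %d trials in at least one condition",
                           min_trials)
  keep <- is.na(reason)
  out <- subjects[keep, , drop = FALSE]
  attr(out, "excluded") <- bind_cols(subjects[!keep, , drop = FALSE],
                                     tibble(reason = reason[!keep]))
  out
}
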