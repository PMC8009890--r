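# Topographic primitives, AAHC clustering, template fitting, features and
# explained variance, each against direct or exhaustive oracles.

test_that("GFP and topography normalization follow their closed forms", {
  expect_equal(gfp(c(0, 0, 0, 0)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(c(3, -1, -1, -1)), sqrt(3))
  expect_error(gfp(5), "2 channels")

  expect_equal(normalize_topography(c(2, -2)), c(1, -1))
  v <- normalize_topography(c(0.3, -1.2, 0.5, 0.4))
  expect_equal(normalize_topography(v), v, tolerance = 1e-12)
  expect_equal(normalize_topography(c(4, 0, 0, 0)),
               c(3, -1, -1, -1) / sqrt(3))
  expect_error(normalize_topography(c(2, 2, 2)), "flat")
})

test_that("spatial correlation is signed Pearson across channels", {
  v <- c(1.2, -0.4, 2, -2.8)
  expect_equal(spatial_correlation(v, v), 1)
  expect_equal(spatial_correlation(v, -v), -1)
  expect_equal(spatial_correlation(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  # equals stats::cor on average-referenced vectors
  set.seed(2)
  a <- rnorm(16); b <- rnorm(16)
  expect_equal(spatial_correlation(a, b), cor(a, b), tolerance = 1e-12)
  expect_error(spatial_correlation(c(1, 1), c(1, -1)), "flat")
  expect_error(spatial_correlation(1:3, 1:4), "equal channel")
})

test_that("AAHC separates noise-free duplicate topographies exactly", {
  maps <- fixture_maps(2, 16, seed = 5)
  samples <- rbind(maps$maps[rep(1, 6), ] * 2, maps$maps[rep(2, 6), ] * 3)
  cl <- aahc_cluster(samples, 2)
  cc <- abs(cl$maps %*% t(maps$maps) / 16)
  expect_equal(unname(sort(apply(cc, 1, max))), c(1, 1), tolerance = 1e-9)
  # assignment groups the duplicates
  a <- attr(cl, "assignment")
  expect_equal(length(unique(a[1:6])), 1)
  expect_equal(length(unique(a[7:12])), 1)
  expect_false(a[1] == a[7])
})

test_that("k_target equal to the sample count keeps every sample", {
  set.seed(6)
  samples <- matrix(rnorm(5 * 8), 5)
  cl <- aahc_cluster(samples, 5)
  norm <- t(apply(samples, 1, normalize_topography))
  cc <- abs(cl$maps %*% t(norm) / 8)
  expect_equal(unname(apply(cc, 1, max)), rep(1, 5), tolerance = 1e-9)
  expect_error(aahc_cluster(samples, 6), "between 2")
})

test_that("AAHC matches exhaustive best-partition clustering at low noise", {
  set.seed(9)
  n_ch <- 8
  planted <- make_maps(3, n_ch, max_abs_corr = 0.5, seed = 13)$maps
  idx <- rep(1:3, length.out = 10)
  samples <- planted[idx, ] * c(2, 2.5, 3)[idx] +
    matrix(rnorm(10 * n_ch, sd = 0.15), 10)
  g <- apply(samples, 1, gfp)
  xn <- t(apply(samples, 1, normalize_topography))

  partition_gev <- function(lab) {
    tot <- 0
    for (cl in unique(lab)) {
      mem <- lab == cl
      m <- colMeans(xn[mem, , drop = FALSE])
      m <- m - mean(m)
      gm <- sqrt(mean(m^2))
      if (gm == 0) next
      m <- m / gm
      cc <- xn[mem, , drop = FALSE] %*% m / n_ch
      tot <- tot + sum((g[mem] * cc)^2)
    }
    tot / sum(g^2)
  }
  # exhaustive search over all assignments of 10 samples to 3 labels
  grid <- expand.grid(rep(list(1:3), 10))
  best <- -Inf; best_lab <- NULL
  for (r in seq_len(nrow(grid))) {
    lab <- unlist(grid[r, ], use.names = FALSE)
    if (length(unique(lab)) != 3) next
    v <- partition_gev(lab)
    if (v > best) { best <- v; best_lab <- lab }
  }
  cl <- aahc_cluster(samples, 3)
  a <- attr(cl, "assignment")
  # same partition up to label permutation
  expect_equal(length(unique(paste(a, best_lab))), 3)
  expect_equal(partition_gev(a), best, tolerance = 1e-9)
})

test_that("template fitting labels samples by highest spatial correlation", {
  maps <- fixture_maps()
  e <- fixture_erp(noise_sd = 0.4, seed = 21)
  seg <- fit_templates(e, maps, window = c(0, 794))
  # brute-force per-sample argmax oracle
  tms <- erp_times(e)
  idx <- which(tms >= 0 & tms <= 794)
  oracle <- vapply(idx, function(j) {
    cors <- vapply(seq_len(maps$k), function(m) {
      spatial_correlation(e$data[, j], maps$maps[m, ])
    }, numeric(1))
    which.max(cors)
  }, integer(1))
  expect_equal(seg$label, oracle)
  expect_equal(seg$gfp, unname(apply(e$data[, idx], 2, gfp)))

  # exact scaled copy of a map gets label and correlation 1
  s <- 2.5 * maps$maps[3, ]
  e3 <- erp_waveform(cbind(s, s), fs = 500, t0_offset = 0,
                     channel_ids = maps$channel_ids)
  seg3 <- fit_templates(e3, maps, window = c(0, 2))
  expect_equal(seg3$label, c(3, 3))
  expect_equal(seg3$spatial_corr, c(1, 1), tolerance = 1e-12)

  # channel mismatch is an error
  bad <- erp_waveform(e$data, fs = 500, t0_offset = -200,
                      channel_ids = rev(e$channel_ids))
  expect_error(fit_templates(bad, maps), "channel ids")
})

test_that("correlation ties go to the lowest map index", {
  # two orthogonal 4-channel maps; a sample equidistant from both
  m <- ms_maps(rbind(c(1, -1, 1, -1), c(1, 1, -1, -1)))
  s <- normalize_topography(c(1, 0, 0, -1))  # corr 0.5 with both maps
  e <- erp_waveform(matrix(s), fs = 500, t0_offset = 0)
  seg <- fit_templates(e, m, window = c(0, 0))
  expect_equal(
    spatial_correlation(s, m$maps[1, ]),
    spatial_correlation(s, m$maps[2, ]))
  expect_equal(seg$label, 1L)
})

test_that("flat samples carry the previous (or first non-flat) label", {
  m <- fixture_maps(2, 8, seed = 2)
  dat <- cbind(0, 2 * m$maps[2, ], 0, 0, 1.5 * m$maps[1, ], 0)
  e <- erp_waveform(dat, fs = 500, t0_offset = 0,
                    channel_ids = m$channel_ids)
  seg <- fit_templates(e, m, window = c(0, 10))
  expect_equal(seg$label, c(2L, 2L, 2L, 2L, 1L, 1L))
  expect_true(all(is.na(seg$spatial_corr[c(1, 3, 4, 6)])))
  # durations still conserve the window
  f <- extract_features(seg, feature_window = c(0, 10))
  expect_equal(sum(f$duration_ms), 12)
})

test_that("features count occupancy and average raw GFP per map", {
  m <- fixture_maps(2, 8, seed = 2)
  dat <- cbind(1 * m$maps[1, ], 3 * m$maps[1, ],
               2 * m$maps[2, ], 2 * m$maps[2, ], 2 * m$maps[2, ])
  e <- erp_waveform(dat, fs = 500, t0_offset = 0,
                    channel_ids = m$channel_ids)
  seg <- fit_templates(e, m, window = c(0, 8))
  f <- extract_features(seg, feature_window = c(0, 8))
  expect_equal(f$duration_ms, c(4, 6))         # counts x 2 ms at 500 Hz
  expect_equal(f$mean_gfp, c(2, 2))            # (1+3)/2 and (2+2+2)/3
  expect_true(all(f$present))
  # an absent map has zero duration and missing mean GFP
  f2 <- extract_features(seg, k = 3, feature_window = c(0, 8))
  expect_equal(f2$duration_ms[3], 0)
  expect_true(is.na(f2$mean_gfp[3]))
  expect_false(f2$present[3])
})

test_that("durations conserve the window and scale equivariance holds", {
  maps <- fixture_maps()
  e <- fixture_erp(noise_sd = 0.5, seed = 33)
  seg <- fit_templates(e, maps, window = c(0, 794))
  f <- extract_features(seg, feature_window = c(300, 794))
  expect_equal(sum(f$duration_ms), 496)
  # multiplying the ERP by alpha > 0 preserves labels and durations and
  # scales mean GFP by alpha
  e2 <- e; e2$data <- 2.5 * e$data
  seg2 <- fit_templates(e2, maps, window = c(0, 794))
  expect_equal(seg2$label, seg$label)
  f2 <- extract_features(seg2, feature_window = c(300, 794))
  expect_equal(f2$duration_ms, f$duration_ms)
  expect_equal(f2$mean_gfp, 2.5 * f$mean_gfp)
})

test_that("explained variance matches hand-computed GEV on a toy instance", {
  m <- fixture_maps(2, 8, seed = 14)
  set.seed(15)
  dat <- sapply(1:10, function(i) {
    2 * m$maps[1 + i %% 2, ] + rnorm(8, sd = 0.3)
  })
  e <- erp_waveform(dat, fs = 500, t0_offset = 0,
                    channel_ids = m$channel_ids)
  ev <- explained_variance(e, m, window = c(0, 18))
  g <- apply(dat, 2, gfp)
  cors <- apply(dat, 2, function(s) {
    max(spatial_correlation(s, m$maps[1, ]),
        spatial_correlation(s, m$maps[2, ]))
  })
  expect_equal(ev, sum((g * cors)^2) / sum(g^2), tolerance = 1e-12)
  # exact map data: GEV 1; orthogonal maps: GEV 0
  e1 <- erp_waveform(cbind(2 * m$maps[1, ], 3 * m$maps[2, ]), 500, 0,
                     channel_ids = m$channel_ids)
  expect_equal(explained_variance(e1, m, c(0, 2)), 1, tolerance = 1e-12)
  # build maps orthogonal to the data in a 4-channel space
  orth <- ms_maps(rbind(c(1, -1, 1, -1), c(1, -1, -1, 1)))
  e0 <- erp_waveform(matrix(c(1, 1, -1, -1)), 500, 0)
  expect_equal(explained_variance(e0, orth, c(0, 0)), 0, tolerance = 1e-12)
})

test_that("noise-free cohorts are perfectly identifiable downstream", {
  cfg <- sim_config(group_sizes = c("noFH-noASD" = 3, "FH-noASD" = 2,
                                    "FH-ASD" = 2), noise_sd = 0, seed = 17)
  co <- simulate_cohort(cfg)
  for (i in seq_len(nrow(co$erps))) {
    e <- co$erps$erp[[i]]
    seg <- fit_templates(e, co$maps, window = c(0, 794))
    expect_equal(seg$label, attr(e, "planted_labels"))
    f <- extract_features(seg, feature_window = c(300, 794))
    truth <- co$truth |>
      dplyr::filter(subject_id == co$erps$subject_id[i],
                    condition == co$erps$condition[i])
    expect_equal(f$duration_ms, truth$duration_ms)
    expect_equal(f$mean_gfp[f$present], truth$mean_gfp[truth$present],
                 tolerance = 1e-9)
  }
})

test_that("map-count selection finds the planted k and floors gracefully", {
  cfg <- sim_config(group_sizes = c("noFH-noASD" = 12, "FH-noASD" = 2,
                                    "FH-ASD" = 2), noise_sd = 0, seed = 23)
  co <- simulate_cohort(cfg)
  ref <- co$erps |>
    dplyr::filter(subject_id %in%
                    co$subjects$subject_id[co$subjects$group == "noFH-noASD"],
                  condition == "FD")
  mod <- select_n_maps(ref, k_range = 2:6, n_splits = 6, n_rand = 100,
                       seed = 3)
  expect_equal(mod$k_opt, 4)
  cc <- abs(mod$maps$maps %*% t(co$maps$maps) / 64)
  expect_true(all(apply(cc, 1, max) >= 0.99))

  # single planted map: no candidate count improves on the floor
  m1 <- make_maps(2, 32, seed = 2)
  plan1 <- data.frame(map = 1, duration_ms = 796, gfp = 2.5)
  erps1 <- lapply(1:10, function(i) {
    simulate_erp(m1, plan1, noise_sd = 0.5, seed = 100 + i,
                 subject_id = paste0("S", i))
  })
  expect_warning(mod1 <- select_n_maps(erps1, k_range = 2:4, n_splits = 5,
                                       n_rand = 100, seed = 3),
                 "floor")
  expect_equal(mod1$k_opt, 2)

  # tidy/glance accessors
  expect_s3_class(tidy(mod), "tbl_df")
  expect_equal(glance(mod)$k_opt, 4)
})

test_that("GEV cannot decrease as the template set grows (polarity-free)", {
  # with absolute correlations the winning correlation is a max over maps,
  # so adding maps can only improve the fit at every sample
  maps4 <- fixture_maps(4, 16, seed = 6)
  maps2 <- ms_maps(maps4$maps[1:2, ])
  set.seed(7)
  dat <- matrix(rnorm(16 * 30), 16)
  e <- erp_waveform(dat, fs = 500, t0_offset = 0,
                    channel_ids = maps4$channel_ids)
  ev2 <- explained_variance(e, maps2, c(0, 58), ignore_polarity = TRUE)
  ev4 <- explained_variance(e, maps4, c(0, 58), ignore_polarity = TRUE)
  expect_gte(ev4, ev2)
})
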