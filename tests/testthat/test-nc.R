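# Nc component features: referencing, region averaging, mean amplitude,
# peak latency and difference scores.

test_that("average reference removes the channel mean and is idempotent", {
  e <- erp_waveform(rbind(c(2, 3), c(2, 1)), fs = 500, t0_offset = 0)
  r <- average_reference(e)
  expect_equal(unname(r$data[, 1]), c(0, 0))
  expect_equal(unname(r$data[, 2]), c(1, -1))
  expect_equal(average_reference(r)$data, r$data)
  expect_error(average_reference(erp_waveform(matrix(1, 1, 4), 500, 0)),
               "2 channels")
})

test_that("region_mean equals the per-sample mean over region channels", {
  set.seed(4)
  dat <- matrix(rnorm(5 * 20), 5,
                dimnames = list(sprintf("E%d", 1:5), NULL))
  e <- erp_waveform(dat, fs = 500, t0_offset = 0)
  mont <- montage(sprintf("E%d", 1:5),
                  c("frontal-left", "frontal-left", "frontal-left",
                    "other", "other"))
  w <- region_mean(e, mont, "frontal-left")
  ref <- sweep(dat, 2, colMeans(dat))   # computed on average-referenced data
  expect_equal(w$amplitude, colMeans(ref[1:3, ]))
  # single-channel region returns that channel unchanged
  mont1 <- montage("E4", "frontal-central")
  w1 <- region_mean(e, mont1, "frontal-central")
  expect_equal(w1$amplitude, ref[4, ], ignore_attr = TRUE)
  expect_error(region_mean(e, mont, "occipital"), "unknown region")
  mont_missing <- montage("E99", "frontal-right")
  expect_error(region_mean(e, mont_missing, "frontal-right"), "no channels")
})

test_that("Nc mean amplitude matches direct formula evaluation", {
  tms <- seq(-200, 794, by = 2)
  flat <- tibble::tibble(time_ms = tms, amplitude = -5)
  expect_equal(suppressMessages(nc_mean_amplitude(flat, c(300, 800))), -5)
  # one -10 µV sample among the 248 in-window samples of a zero waveform
  w <- tibble::tibble(time_ms = tms, amplitude = 0)
  w$amplitude[w$time_ms == 500] <- -10
  n_in <- sum(tms >= 300 & tms <= 794)
  expect_equal(suppressMessages(nc_mean_amplitude(w, c(300, 800))),
               -10 / n_in)
  # locality: values outside the window cannot change the mean
  w2 <- w; w2$amplitude[w2$time_ms < 300] <- 99
  expect_equal(suppressMessages(nc_mean_amplitude(w2, c(300, 800))),
               suppressMessages(nc_mean_amplitude(w, c(300, 800))))
  # linearity in the waveform
  w3 <- tibble::tibble(time_ms = tms, amplitude = rnorm(length(tms)))
  expect_equal(suppressMessages(nc_mean_amplitude(
    dplyr::mutate(w3, amplitude = 3 * amplitude), c(300, 794))),
    3 * suppressMessages(nc_mean_amplitude(w3, c(300, 794))))
})

test_that("Nc peak latency takes the earliest most-negative sample", {
  tms <- seq(-200, 794, by = 2)
  w <- tibble::tibble(time_ms = tms, amplitude = 0)
  w$amplitude[w$time_ms == 450] <- -3
  expect_equal(suppressMessages(nc_peak_latency(w, c(300, 800))), 450)
  # tie at 400 and 600 ms resolves to 400
  w$amplitude[w$time_ms %in% c(400, 600)] <- -7
  expect_equal(suppressMessages(nc_peak_latency(w, c(300, 800))), 400)
  # monotone decreasing waveform peaks at the window end (794 with clip)
  w2 <- tibble::tibble(time_ms = tms, amplitude = -seq_along(tms))
  expect_equal(suppressMessages(nc_peak_latency(w2, c(300, 800))), 794)
  # invariance under positive affine amplitude transforms
  w3 <- tibble::tibble(time_ms = tms, amplitude = sin(tms / 90))
  expect_equal(
    suppressMessages(nc_peak_latency(
      dplyr::mutate(w3, amplitude = 2 * amplitude + 5), c(300, 794))),
    suppressMessages(nc_peak_latency(w3, c(300, 794))))
})

test_that("difference scores are plain antisymmetric differences", {
  expect_equal(difference_score(-6.2, -4.0), -2.2)
  expect_equal(difference_score(3, 3), 0)
  expect_equal(difference_score(1.5, -2), -difference_score(-2, 1.5))
})

test_that("nc_features and difference scores cover regions and contrasts", {
  cfg <- sim_config(group_sizes = c("noFH-noASD" = 2, "FH-noASD" = 2,
                                    "FH-ASD" = 2), seed = 31)
  co <- simulate_cohort(cfg)
  nc <- suppressMessages(nc_features(co$erps))
  expect_equal(nrow(nc), 6 * 3 * 4)  # subjects x conditions x regions
  expect_true(all(nc$peak_latency >= 300 & nc$peak_latency <= 794))
  d <- nc_difference_scores(nc)
  expect_setequal(unique(d$contrast), c("FD-Noise", "FA-Noise"))
  one <- nc |>
    dplyr::filter(subject_id == "S001", region == "frontal")
  expect_equal(
    d$mean_amplitude_diff[d$subject_id == "S001" & d$region == "frontal" &
                            d$contrast == "FD-Noise"],
    one$mean_amplitude[one$condition == "FD"] -
      one$mean_amplitude[one$condition == "Noise"])
})

test_that("peak latency lands inside a planted strongly negative segment", {
  # plant a map that is strongly negative over the frontal channels in the
  # 430-650 ms segment and weaker elsewhere
  set.seed(8)
  n_ch <- 64
  frontal <- default_montage(n_ch)
  front_idx <- which(frontal$region != "other")
  m4 <- rnorm(n_ch); m4[front_idx] <- -abs(m4[front_idx]) - 2
  other <- matrix(rnorm(3 * n_ch), 3)
  maps <- ms_maps(rbind(other, m4))
  plan <- tibble::tibble(map = c(1, 2, 3, 4, 1),
                         duration_ms = c(150, 200, 80, 220, 146),
                         gfp = c(1, 1.2, 1, 3.5, 1))
  e <- simulate_erp(maps, plan, noise_sd = 0.1, seed = 2,
                    subject_id = "S1", condition = "FD")
  w <- region_mean(e, frontal, "frontal-central")
  lat <- suppressMessages(nc_peak_latency(w, c(300, 794)))
  expect_gte(lat, 430)
  expect_lte(lat, 650)
})
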