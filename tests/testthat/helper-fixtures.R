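# Shared fixtures: tiny map sets, plans and ERPs built in code.

fixture_maps <- function(n_maps = 4, n_channels = 64, seed = 3) {
  make_maps(n_maps, n_channels, max_abs_corr = 0.5, seed = seed)
}

fixture_plan <- function(total = 796) {
  tibble::tibble(map = c(1, 2, 3, 4),
                 duration_ms = c(150, 200, 80, total - 430),
                 gfp = c(2.2, 2.6, 1.8, 3.2))
}

fixture_erp <- function(maps = fixture_maps(), plan = fixture_plan(),
                        noise_sd = 0, seed = 7, condition = "FD",
                        subject_id = "S1") {
  simulate_erp(maps, plan, noise_sd = noise_sd, seed = seed,
               subject_id = subject_id, condition = condition)
}

# A small feature table with a known linear outcome, for the prediction
# module tests.
fixture_feature_table <- function(n = 60, p = 8, seed = 1,
                                  beta = NULL, noise_sd = 0,
                                  separation = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", seq_len(p))))
  y_bin <- rep(c(FALSE, TRUE), length.out = n)
  if (separation > 0) {
    x[y_bin, 1:2] <- x[y_bin, 1:2] + separation
  }
  beta <- beta %||% rep(0, p)
  tb <- tibble::as_tibble(x)
  tb$subject_id <- sprintf("S%03d", seq_len(n))
  tb$asd_outcome <- y_bin
  tb$vabs_socialization <- 100 + drop(x %*% beta) + rnorm(n, 0, noise_sd)
  attr(tb, "feature_cols") <- paste0("f", seq_len(p))
  tb
}

`%||%` <- function(a, b) if (is.null(a)) b else a
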