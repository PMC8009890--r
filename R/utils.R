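# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Bit-reproducibility of every stochastic
# operation in the package rests on this helper.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Sample times in ms for a waveform: first sample at t0_offset, step 1000/fs.
sample_times <- function(n, fs, t0_offset) {
  t0_offset + (seq_len(n) - 1L) * 1000 / fs
}

# Indices of samples falling inside a closed window [w1, w2] (ms).
window_index <- function(times, window) {
  which(times >= window[1] & times <= window[2])
}

# Clip an analysis window to the epoch actually covered by `times`,
# messaging when a bound had to move (e.g. a 300-800 ms window against an
# epoch ending at 794 ms).
clip_window <- function(window, times, label = "window") {
  lo <- max(window[1], min(times))
  hi <- min(window[2], max(times))
  if (lo > hi) {
    abort(sprintf("%s [%g, %g] ms does not overlap the epoch [%g, %g] ms",
                  label, window[1], window[2], min(times), max(times)))
  }
  if (lo != window[1] || hi != window[2]) {
    inform(sprintf("%s clipped from [%g, %g] to [%g, %g] ms to fit the epoch",
                   label, window[1], window[2], lo, hi),
           .frequency = "regularly", .frequency_id = paste0("clip_", label))
  }
  c(lo, hi)
}

# Rank-based (Wilcoxon-Mann-Whitney) ROC AUC of scores against a logical
# outcome. Used in the genetic-algorithm fitness hot loop; cross-checked
# against pROC in the test suite.
auc_wmw <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC requires both classes to be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Wilson score interval for a binomial proportion (returns fractions).
wilson_ci <- function(k, n, level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

# Hanley-McNeil confidence interval for an ROC AUC.
hanley_mcneil_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(max(v, 0))
  c(max(0, auc - half), min(1, auc + half))
}

# Stratified fold assignment: within each class, shuffle and deal folds
# round-robin so every fold keeps both classes whenever class sizes allow.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Largest-remainder apportionment of `total` across classes proportional to
# `counts` (used by stratified_split so the train size matches
# round(train_fraction * n) exactly).
apportion <- function(counts, total) {
  quota <- counts / sum(counts) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
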