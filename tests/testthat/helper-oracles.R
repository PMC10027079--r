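# Independent oracles used to validate the package implementations.
# These are deliberately written as plain, direct computations that share
# no code with the package internals.

# Brute-force sample entropy via full pairwise Chebyshev distance
# matrices between embedded templates.
sampen_bruteforce <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  emb <- embed(x, m + 1)[, (m + 1):1, drop = FALSE]  # rows: x[i..i+m]
  stopifnot(nrow(emb) == nt)
  dmat_m <- matrix(0, nt, nt)
  for (k in seq_len(m)) {
    dmat_m <- pmax(dmat_m, abs(outer(emb[, k], emb[, k], "-")))
  }
  dmat_m1 <- pmax(dmat_m, abs(outer(emb[, m + 1], emb[, m + 1], "-")))
  ut <- upper.tri(dmat_m)
  B <- sum(dmat_m[ut] <= r)
  A <- sum(dmat_m1[ut] <= r)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Exhaustive Mann-Whitney two-sided p-value for small tie-free samples,
# enumerating every assignment of the pooled values to the two groups.
# Follows the exact-test convention of doubling the smaller tail.
mw_enumeration_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_obs <- sum(outer(x, y, ">"))
  combos <- combn(nx + ny, nx)
  u_all <- apply(combos, 2, function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">"))
  })
  if (u_obs > nx * ny / 2) {
    p <- 2 * mean(u_all >= u_obs)
  } else {
    p <- 2 * mean(u_all <= u_obs)
  }
  min(1, p)
}

# Repeated-measures ANOVA F from explicit sums of squares.
rm_anova_bruteforce <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  ms_cond <- ss_cond / (k - 1)
  ms_err <- ss_err / ((k - 1) * (n - 1))
  ms_cond / ms_err
}

# ICC(3,1) recomputed directly from the mean-square definitions.
icc31_bruteforce <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - grand)^2) - msr * (n - 1) - msc * (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

# Straightforward epoch-scanning re-implementation of the macro
# architecture metrics, following the same written definitions as
# macro_architecture() but coded independently (explicit loops).
macro_oracle <- function(hyp, epoch_min = 0.5, per_lat_run = 10,
                         min_nrem = 30, min_rem = 10) {
  n <- length(hyp)
  is_sleep <- hyp != "W"
  tib <- n * epoch_min
  tst <- sum(is_sleep) * epoch_min
  if (tst == 0) {
    return(list(TST = 0, WASO = 0, SLP_EFF = 0, SLP_MA_EFF = NA,
                REM_LAT = NA, PER_LAT = NA, NREMC = NA, NREMC_count = 0))
  }
  onset <- 1; while (!is_sleep[onset]) onset <- onset + 1
  last <- n; while (!is_sleep[last]) last <- last - 1
  waso <- 0
  for (i in onset:last) if (hyp[i] == "W") waso <- waso + epoch_min
  rem_lat <- NA
  for (i in seq_len(n)) {
    if (hyp[i] == "REM") { rem_lat <- (i - onset) * epoch_min; break }
  }
  per_lat <- NA
  run <- 0
  for (i in seq_len(n)) {
    if (is_sleep[i]) run <- run + 1 else run <- 0
    if (run == per_lat_run) { per_lat <- (i - per_lat_run) * epoch_min; break }
  }
  # cycles: scan the sleep period epoch by epoch
  period <- hyp[onset:last]
  cycles <- c()
  block_start <- 1
  closed_any <- FALSE
  i <- 1
  while (i <= length(period)) {
    if (period[i] == "REM") {
      j <- i
      while (j < length(period) && period[j + 1] == "REM") j <- j + 1
      if (i <= block_start) {
        block_start <- j + 1
      } else if (j - i + 1 >= min_rem || !closed_any) {
        n_nrem <- 0
        for (q in block_start:(i - 1)) {
          if (period[q] %in% c("N1", "N2", "N3")) n_nrem <- n_nrem + 1
        }
        if (n_nrem >= min_nrem) cycles <- c(cycles, j - block_start + 1)
        closed_any <- TRUE
        block_start <- j + 1
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  list(TST = tst, WASO = waso, SLP_EFF = 100 * tst / tib,
       SLP_MA_EFF = 100 * tst / ((last - onset + 1) * epoch_min),
       REM_LAT = rem_lat, PER_LAT = per_lat,
       NREMC = if (length(cycles)) mean(cycles) * epoch_min else NA,
       NREMC_count = length(cycles))
}

# Random hypnogram with runs (not a valid night necessarily; stresses the
# metric definitions).
random_hypnogram <- function(n, seed) {
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    st <- sample(c("W", "N1", "N2", "N3", "REM"), 1,
                 prob = c(0.15, 0.1, 0.3, 0.2, 0.25))
    len <- sample(1:25, 1)
    out <- c(out, rep(st, len))
  }
  out[seq_len(n)]
}

# Build an epoched_signal directly from a samples x channels matrix.
make_epochs <- function(data, fs, stages, labels = "C4-M1",
                        classes = "EEG") {
  rec <- new_recording(as.matrix(data), fs, labels, classes)
  segment_epochs(rec, stages)
}

# Hann-enveloped spindle / biphasic SO fixture helpers.
spindle_fixture_events <- function(onsets, durs, freqs, amps,
                                   channel = "C4-M1") {
  ground_truth_events(channel = rep(channel, length(onsets)),
                      kind = rep("spindle_slow", length(onsets)),
                      onset_s = onsets, offset_s = onsets + durs,
                      freq_hz = freqs, amp_uv = amps)
}

so_fixture <- function(neg_amp, pos_amp, neg_dur, pos_dur, t0 = 60,
                       len_s = 120, fs = 500) {
  x <- numeric(len_s * fs)
  ev <- ground_truth_events(channel = "a", kind = "so", onset_s = t0,
                            offset_s = t0 + neg_dur + pos_dur,
                            neg_amp_uv = neg_amp, pos_amp_uv = pos_amp,
                            neg_dur_s = neg_dur)
  inject_events(x, fs, ev)
}
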