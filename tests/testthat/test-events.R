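# Event-level fixtures are built at a few controlled amplitudes relative
# to the sigma-band RMS of the background noise, so the detector criteria
# (4.5x mean for >= 0.3 s inside 2x for >= 0.5 s) are clearly met or
# clearly violated by construction.

spindle_bg <- function(seed = 10, len_s = 120, fs = 500) {
  x <- generate_colored_noise(len_s, fs, 1, 30, seed = seed)
  sig <- sqrt(mean(somnarch:::fir_bandpass(x, fs, 9, 13, 1)^2))
  list(x = x, sigma = sig, fs = fs, hyp = rep("N2", len_s / 30))
}

test_that("a clear injected spindle is recovered once, weak bursts are not", {
  bg <- spindle_bg()
  ev <- spindle_fixture_events(60, 1.0, 11, 10 * bg$sigma)
  y <- inject_events(bg$x, bg$fs, ev)
  det <- detect_spindles(y, bg$fs, bg$hyp, spindle_params(fc = 11))
  expect_equal(nrow(det), 1)
  overlap <- min(det$offset_s, 61) - max(det$onset_s, 60)
  expect_gte(overlap, 0.5)
  expect_lt(abs(det$onset_s - 60), 0.3)

  # a 0.25 s burst at the same amplitude fails the core-duration rule
  ev2 <- spindle_fixture_events(60, 0.25, 11, 10 * bg$sigma)
  det2 <- detect_spindles(inject_events(bg$x, bg$fs, ev2), bg$fs, bg$hyp,
                          spindle_params(fc = 11))
  expect_equal(nrow(det2), 0)

  expect_error(detect_spindles(bg$x, bg$fs, rep("REM", 4),
                               spindle_params(fc = 11)), "normalization")
})

test_that("raising spindle amplitude never loses the detection", {
  bg <- spindle_bg(seed = 11)
  found <- vapply(c(10, 14, 18, 25), function(k) {
    ev <- spindle_fixture_events(60, 0.9, 11, k * bg$sigma)
    det <- detect_spindles(inject_events(bg$x, bg$fs, ev), bg$fs, bg$hyp,
                           spindle_params(fc = 11))
    any(det$onset_s < 61 & det$offset_s > 60)
  }, TRUE)
  expect_true(all(diff(found) >= 0))
  expect_true(found[1])
})

test_that("spindle detection is translation-equivariant", {
  bg <- spindle_bg(seed = 12)
  ev <- spindle_fixture_events(60, 1.0, 11, 12 * bg$sigma)
  y <- inject_events(bg$x, bg$fs, ev)
  k <- 500  # 1 s
  n <- length(y)
  d1 <- detect_spindles(y[1:(n - k)], bg$fs, bg$hyp, spindle_params(fc = 11))
  d2 <- detect_spindles(y[(k + 1):n], bg$fs, rep("N2", 4),
                        spindle_params(fc = 11))
  hit1 <- d1[d1$onset_s > 55 & d1$onset_s < 65, ]
  hit2 <- d2[d2$onset_s > 54 & d2$onset_s < 64, ]
  expect_equal(nrow(hit1), 1)
  expect_equal(nrow(hit2), 1)
  expect_equal(hit2$onset_s, hit1$onset_s - k / bg$fs, tolerance = 0.01)
  expect_equal(hit2$peak_s, hit1$peak_s - k / bg$fs, tolerance = 0.01)
})

test_that("detected spindles are non-overlapping after merging", {
  bg <- spindle_bg(seed = 13, len_s = 300)
  onsets <- seq(20, 280, by = 13)
  ev <- spindle_fixture_events(onsets, 1.0, 11, 12 * bg$sigma)
  det <- detect_spindles(inject_events(bg$x, bg$fs, ev), bg$fs,
                         rep("N2", 10), spindle_params(fc = 11))
  expect_gt(nrow(det), 2)
  expect_true(all(diff(det$onset_s) > 0))
  expect_true(all(det$onset_s[-1] >= det$offset_s[-nrow(det)]))
  expect_true(all(det$dur_s <= 3))
})

test_that("slow-oscillation criteria are individually necessary", {
  fs <- 500
  hyp <- rep("N3", 4)
  det_of <- function(x) detect_slow_oscillations(x, fs, hyp,
                                                 target_stages = "N3")
  # compliant biphasic wave (filtered: ~ -51 uV, p2p ~ 104, 0.64/0.54 s)
  expect_equal(nrow(det_of(so_fixture(-80, 50, 0.8, 0.5))), 1)
  # each single-criterion violation in the filtered domain is rejected
  expect_equal(nrow(det_of(so_fixture(-50, 60, 0.8, 0.5))), 0)   # neg peak
  expect_equal(nrow(det_of(so_fixture(-80, 10, 0.8, 0.5))), 0)   # p2p
  expect_equal(nrow(det_of(so_fixture(-80, 50, 0.15, 0.5))), 0)  # neg dur
  expect_equal(nrow(det_of(so_fixture(-110, 60, 0.8, 1.5))), 0)  # pos dur

  expect_error(det_of(numeric(120 * fs)), "zero crossings")
})

test_that("detected SO metrics match the injected wave after filtering", {
  fs <- 500
  hyp <- rep("N3", 10)
  x <- generate_colored_noise(300, fs, 1.5, 15, seed = 14)
  onsets <- seq(30, 270, length.out = 5)
  ev <- ground_truth_events(channel = rep("a", 5), kind = rep("so", 5),
                            onset_s = onsets, offset_s = onsets + 1.3,
                            neg_amp_uv = -80, pos_amp_uv = 50,
                            neg_dur_s = 0.8)
  det <- detect_slow_oscillations(inject_events(x, fs, ev), fs, hyp)
  expect_gte(nrow(det), 4)
  # amplitudes within filter-distortion tolerance of the filtered truth
  expect_lt(abs(median(det$neg_peak_uv) + 51), 10)
  expect_lt(abs(median(det$p2p_uv) - 104), 15)
  expect_true(all(det$neg_dur_s >= 0.3 & det$neg_dur_s <= 1.5))
  expect_true(all(det$pos_dur_s > 0 & det$pos_dur_s <= 1))
  expect_true(all(det$onset_s < det$peak_s & det$peak_s < det$offset_s))
})

test_that("feature tables summarize events correctly", {
  fs <- 500
  hyp <- rep("N2", 40)  # 20 min
  x <- generate_colored_noise(1200, fs, 1, 30, seed = 15)
  sig <- sqrt(mean(somnarch:::fir_bandpass(x, fs, 9, 13, 1)^2))
  onsets <- seq(30, 1150, length.out = 10)
  ev <- spindle_fixture_events(onsets, 1.0, 11, 12 * sig)
  y <- inject_events(x, fs, ev)
  det <- detect_spindles(y, fs, hyp, spindle_params(fc = 11))
  expect_equal(nrow(det), 10)
  sf <- spindle_features(det, y, fs, hyp, spindle_params(fc = 11))
  expect_equal(sf$DENS, 0.5)             # 10 events / 20 min
  expect_equal(sf$N, 10L)
  expect_lt(abs(sf$FRQ - 11), 0.5)
  expect_lt(abs(sf$FFT - 11), 0.5)
  expect_lte(sf$FWHM, sf$DUR)
  expect_gt(sf$NOSC, 5)

  # empty event list: zero counts, missing summaries
  sf0 <- spindle_features(det[0, ], y, fs, hyp)
  expect_equal(sf0$DENS, 0)
  expect_true(is.na(sf0$DUR))
})

test_that("coupling flags intersecting events once per spindle", {
  sp <- tibble::tibble(kind = "spindle_slow", onset_s = c(10, 30, 50),
                       offset_s = c(11, 31, 51), peak_s = c(10.5, 30.5, 50.5))
  so <- tibble::tibble(kind = "so", onset_s = c(10.2, 50.9, 51.0),
                       offset_s = c(10.8, 51.2, 52.5), peak_s = c(10.4, 51, 51.5))
  out <- couple_overlap(sp, so)
  expect_equal(out$coupled, c(TRUE, FALSE, TRUE))
  expect_equal(sum(out$coupled), 2)
  # disjoint
  out0 <- couple_overlap(sp, so[so$onset_s > 100, ])
  expect_equal(sum(out0$coupled), 0)
})

test_that("time-locked averaging recovers the waveform and obeys 1/sqrt(n)", {
  fs <- 200
  proto <- sin(2 * pi * 11 * seq(-1, 1, by = 1 / fs)) *
    exp(-seq(-1, 1, by = 1 / fs)^2 / 0.1)
  place <- function(n_ev, noise_sd, seed) {
    set.seed(seed)
    x <- rnorm(fs * 200, 0, noise_sd)
    centers <- seq(5, 195, length.out = n_ev)
    hw <- (length(proto) - 1) / 2
    for (c0 in centers) {
      # proto center lands on the anchor sample floor(c0 * fs) + 1
      ctr <- floor(c0 * fs) + 1
      idx <- (ctr - hw):(ctr + hw)
      x[idx] <- x[idx] + proto
    }
    list(x = x, ev = tibble::tibble(peak_s = centers))
  }
  # zero noise: exact recovery
  z <- place(4, 0, 1)
  avg <- time_locked_average(z$x, fs, z$ev, half_window_s = 1)
  expect_equal(avg$mean_uv, proto, tolerance = 1e-12)

  # residual RMS shrinks roughly 1/sqrt(n) from 4 to 64 events
  rms_resid <- function(n_ev) {
    z <- place(n_ev, 1, 2)
    avg <- time_locked_average(z$x, fs, z$ev, half_window_s = 1)
    sqrt(mean((avg$mean_uv - proto)^2))
  }
  r4 <- rms_resid(4); r64 <- rms_resid(64)
  expect_lt(r64, r4 / 2.5)

  # events at the edge are excluded; error when none remain
  edge <- tibble::tibble(peak_s = 0.1)
  expect_error(time_locked_average(rnorm(fs * 10), fs, edge,
                                   half_window_s = 1), "full window")
  mix <- tibble::tibble(peak_s = c(0.1, 5))
  avg2 <- time_locked_average(rnorm(fs * 10), fs, mix, half_window_s = 1)
  expect_equal(attr(avg2, "n_excluded"), 1)
  expect_s3_class(plot_time_locked(avg2), "ggplot")
})
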