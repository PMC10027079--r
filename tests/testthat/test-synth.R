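test_that("hypnogram generator respects requested proportions and structure", {
  h <- generate_hypnogram(960, seed = 1)
  frac <- table(factor(h, levels = c("W", "N1", "N2", "N3", "REM"))) / 960
  expect_lt(abs(frac[["N2"]] - 0.50), 0.05)
  expect_lt(abs(frac[["N3"]] - 0.20), 0.05)
  expect_lt(abs(frac[["REM"]] - 0.25), 0.05)
  expect_equal(h[1], "W")

  # convergence at large n
  h2 <- generate_hypnogram(10000, seed = 2)
  frac2 <- table(factor(h2, levels = c("W", "N1", "N2", "N3", "REM"))) / 10000
  expect_lt(abs(frac2[["N2"]] - 0.50), 0.02)
  expect_lt(abs(frac2[["REM"]] - 0.25), 0.02)

  # degenerate all-wake, determinism, validation
  expect_equal(generate_hypnogram(10, proportions = c(W = 1), seed = 3),
               rep("W", 10))
  expect_identical(generate_hypnogram(200, seed = 7),
                   generate_hypnogram(200, seed = 7))
  expect_error(generate_hypnogram(10, proportions = c(W = 0.5)), "sum")
  expect_error(generate_hypnogram(10, proportions = c(XX = 1)), "stage")
})

test_that("colored noise has the target RMS, exponent and determinism", {
  x <- generate_colored_noise(300, 200, 2, rms_uv = 30, seed = 1)
  expect_equal(sqrt(mean(x^2)), 30, tolerance = 1e-12)
  expect_identical(x, generate_colored_noise(300, 200, 2, 30, seed = 1))

  # white noise: flat Welch PSD over 1-30 Hz
  w <- generate_colored_noise(300, 200, 0, 1, seed = 2)
  ep <- make_epochs(w, 200, rep("N2", 10))
  psd <- welch_psd(ep)
  p <- psd$power[psd$freq >= 1]
  expect_lt(max(p) / min(p), 2)

  # alpha = 2: fitted log-log slope near -2
  x2 <- generate_colored_noise(300, 200, 2, 1, seed = 3)
  sl <- spectral_slope(welch_psd(make_epochs(x2, 200, rep("N2", 10))))
  expect_gt(sl$slope, -2.15)
  expect_lt(sl$slope, -1.85)

  expect_error(generate_colored_noise(-1, 100, 1), "positive")
})

test_that("event injection is additive, local and validated", {
  fs <- 100
  x <- sin(2 * pi * 3 * (0:999) / fs)
  expect_identical(inject_events(x, fs, ground_truth_events()), x)

  ev <- spindle_fixture_events(3, 1, 12, 10)
  y <- inject_events(numeric(1000), fs, ev)
  expect_true(all(y[1:300] == 0))
  expect_true(all(y[402:1000] == 0))
  expect_gt(max(abs(y)), 5)

  # additive and local on non-zero background
  y2 <- inject_events(x, fs, ev)
  expect_equal(y2 - x, y, tolerance = 1e-12)

  expect_error(inject_events(numeric(100), fs, ev), "bounds")
})

test_that("filtered injected slow oscillations keep their morphology", {
  # frozen from the brickwall/FIR oracle: a -60 uV half-wave of 0.8 s
  # keeps a filtered minimum near -38 uV (the 0.5-4 Hz bandpass removes
  # the half-wave's DC content)
  fs <- 500
  x <- so_fixture(-60, 40, 0.8, 0.5, fs = fs)
  filt <- somnarch:::fir_bandpass(x, fs, 0.5, 4, 0.5)
  expect_lt(min(filt), -36)
  expect_gt(min(filt), -41)
  # and a deeper -80 uV wave stays below the -40 uV criterion
  x2 <- so_fixture(-80, 50, 0.8, 0.5, fs = fs)
  expect_lt(min(somnarch:::fir_bandpass(x2, fs, 0.5, 4, 0.5)), -45)
})

test_that("generated recordings have the right shape, truth and determinism", {
  h <- generate_hypnogram(10, seed = 4)
  night <- generate_recording(h, fs = 500, seed = 4)
  expect_equal(dim(night$recording$data), c(10 * 30 * 500, 8))
  expect_equal(night$recording$fs, 500)
  expect_equal(night$recording$labels, default_montage()$label)

  night2 <- generate_recording(h, fs = 500, seed = 4)
  expect_identical(night$recording$data, night2$recording$data)
  expect_identical(night$events, night2$events)

  # all-W night with default profiles: no events
  nw <- generate_recording(rep("W", 4), fs = 250, seed = 5)
  expect_equal(nrow(nw$events), 0)

  # events only on EEG channels, in eligible stages, sorted
  ev <- night$events
  if (nrow(ev) > 0) {
    eeg <- default_montage()$label[default_montage()$class == "EEG"]
    expect_true(all(ev$channel %in% eeg))
    expect_true(all(ev$offset_s > ev$onset_s))
    ep_of <- floor(ev$onset_s / 30) + 1
    expect_true(all(h[ep_of] %in% c("N2", "N3")))
  }

  expect_error(generate_recording(c("W", "N2"), profiles = list()),
               "missing profile")
})

test_that("scorer simulation matches its confusion model", {
  h <- generate_hypnogram(300, seed = 6)
  ident <- diag(5)
  dimnames(ident) <- list(c("W", "N1", "N2", "N3", "REM"),
                          c("W", "N1", "N2", "N3", "REM"))
  sc <- simulate_scorers(h, ident, n_scorers = 2, seed = 1)
  expect_identical(sc[[1]], h)
  expect_identical(sc[[2]], h)
  expect_equal(cohen_kappa(sc[[1]], sc[[2]])$estimate, 1)

  # uniform confusion: agreement at chance level
  unif <- matrix(0.2, 5, 5,
                 dimnames = list(c("W", "N1", "N2", "N3", "REM"),
                                 c("W", "N1", "N2", "N3", "REM")))
  h2 <- generate_hypnogram(10000, seed = 8)
  sc2 <- simulate_scorers(h2, unif, n_scorers = 2, seed = 2)
  expect_lt(abs(cohen_kappa(sc2[[1]], sc2[[2]])$estimate), 0.05)

  expect_identical(simulate_scorers(h, unif, 2, seed = 3),
                   simulate_scorers(h, unif, 2, seed = 3))
  bad <- unif; bad[1, 1] <- 0.5
  expect_error(simulate_scorers(h, bad, 1), "stochastic")
})

test_that("paired measurements have the stated ICC structure", {
  d0 <- simulate_paired_measurements(20, 3, 0, seed = 1)
  expect_equal(d0$device_a, d0$device_b)
  expect_equal(icc_consistency(cbind(d0$device_a, d0$device_b))$estimate, 1)

  expect_identical(simulate_paired_measurements(10, 3, 1, seed = 2),
                   simulate_paired_measurements(10, 3, 1, seed = 2))
  expect_error(simulate_paired_measurements(2, 1, 1), ">= 3")

  # asymptotic unbiasedness towards b^2/(b^2+d^2) = 0.9
  est <- vapply(1:150, function(i) {
    d <- simulate_paired_measurements(50, 3, 1, seed = i)
    icc_consistency(cbind(d$device_a, d$device_b))$estimate
  }, 0)
  expect_lt(abs(mean(est) - 0.9), 0.02)
})

test_that("night fixtures roundtrip through plain-text files", {
  h <- generate_hypnogram(4, seed = 9)
  night <- generate_recording(h, montage = default_montage()[c(2, 8), ],
                              fs = 250, seed = 9)
  dir <- tempfile()
  write_night(night, h, dir)
  expect_identical(read_hypnogram(file.path(dir, "hypnogram.txt")), h)
  rec <- read_edf(file.path(dir, "recording.edf"))
  expect_equal(rec$labels, night$recording$labels)
  ev <- utils::read.delim(file.path(dir, "events.tsv"))
  expect_equal(nrow(ev), nrow(night$events))
})
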