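test_that("Welch PSD grid and sinusoid power match the closed form", {
  fs <- 500
  tt <- (0:(30 * fs - 1)) / fs
  ep <- make_epochs(sin(2 * pi * 10 * tt), fs, "N2")
  psd <- welch_psd(ep)
  expect_equal(psd$freq, seq(0.5, 30, 0.5))
  expect_equal(length(psd$freq), 60)
  # unit-amplitude tone: band-integrated power A^2/2 = 0.5 uV^2
  band <- sum(psd$power[psd$freq >= 9.5 & psd$freq <= 10.5]) * 0.5
  expect_lt(abs(band - 0.5), 0.025)

  expect_error(welch_psd(ep, stages = "REM"), "no epochs")
})

test_that("white-noise PSD is flat and scales quadratically with amplitude", {
  fs <- 100
  set.seed(3)
  x <- rnorm(100 * 30 * fs)
  ep <- make_epochs(x, fs, rep("N2", 100))
  psd <- welch_psd(ep)
  expect_lt(max(psd$power) / mean(psd$power), 1.5)

  ep3 <- make_epochs(3 * x[1:(10 * 30 * fs)], fs, rep("N2", 10))
  ep1 <- make_epochs(x[1:(10 * 30 * fs)], fs, rep("N2", 10))
  p3 <- welch_psd(ep3)$power
  p1 <- welch_psd(ep1)$power
  expect_equal(p3, 9 * p1, tolerance = 1e-9)
})

test_that("spectral slope is exact on exact power laws", {
  f <- seq(0.5, 30, 0.5)
  sl2 <- spectral_slope(psd_result(f^-2))
  expect_equal(sl2$slope, -2, tolerance = 1e-12)
  expect_equal(sl2$r2, 1, tolerance = 1e-12)
  sl0 <- spectral_slope(psd_result(rep(2, 60)))
  expect_equal(sl0$slope, 0, tolerance = 1e-12)

  # non-positive bins excluded with a warning
  p <- f^-1; p[10] <- 0
  expect_warning(res <- spectral_slope(psd_result(p)), "non-positive")
  expect_equal(res$n_bins, 59L)
})

test_that("relative band power partitions the grid and normalizes", {
  f <- seq(0.5, 30, 0.5)
  rb <- relative_band_power(psd_result(f^-1.5))
  expect_equal(sum(rb$rel_power), 1, tolerance = 1e-12)
  expect_equal(as.character(rb$band),
               c("slow", "delta", "theta", "alpha", "sigma", "beta"))

  # amplitude-scaling invariance
  rb2 <- relative_band_power(psd_result(7 * f^-1.5))
  expect_equal(rb$rel_power, rb2$rel_power, tolerance = 1e-12)

  # pure 10 Hz tone: alpha dominates
  fs <- 500
  tt <- (0:(30 * fs - 1)) / fs
  psd <- welch_psd(make_epochs(sin(2 * pi * 10 * tt), fs, "N2"))
  rbt <- relative_band_power(psd)
  expect_gte(rbt$rel_power[rbt$band == "alpha"], 0.95)

  # two equal tones at 2 and 10 Hz: delta and alpha split evenly
  x2 <- sin(2 * pi * 2 * tt) + sin(2 * pi * 10 * tt)
  rb3 <- relative_band_power(welch_psd(make_epochs(x2, fs, "N2")))
  expect_lt(abs(rb3$rel_power[rb3$band == "delta"] - 0.5), 0.05)
  expect_lt(abs(rb3$rel_power[rb3$band == "alpha"] - 0.5), 0.05)

  expect_error(relative_band_power(psd_result(rep(0, 60))), "zero total")
})

test_that("slowing index handles symmetry, outliers and degenerate epochs", {
  mk_relp <- function(delta, theta, alpha, beta) {
    n <- length(delta)
    slow <- pmax(1 - delta - theta - alpha - beta - 0.01, 0)
    tibble::tibble(
      epoch = rep(seq_len(n), each = 6),
      channel = "C4-M1", stage = "N2",
      band = factor(rep(c("slow", "delta", "theta", "alpha", "sigma",
                          "beta"), n),
                    levels = c("slow", "delta", "theta", "alpha", "sigma",
                               "beta")),
      rel_power = as.numeric(rbind(slow, delta, theta, alpha, 0.01, beta)))
  }

  # delta + theta == alpha + beta in every epoch -> si = 1 exactly
  set.seed(4)
  d <- runif(12, 0.2, 0.3); t <- runif(12, 0.1, 0.2)
  a <- runif(12, 0.1, 0.3); b <- d + t - a
  si <- slowing_index(mk_relp(d, t, a, b))
  expect_equal(si$si, 1, tolerance = 1e-12)

  # an extreme delta epoch is masked, the rest carry the index
  d2 <- rep(0.25, 21); d2[5] <- 0.25 + 10 * sd(rep_len(c(0.24, 0.26), 21))
  t2 <- rep(0.15, 21); a2 <- rep(0.2, 21); b2 <- rep(0.2, 21)
  d2[-5] <- d2[-5] + rnorm(20, 0, 0.001)
  si2 <- slowing_index(mk_relp(d2, t2, a2, b2))
  expect_equal(si2$n_used, 20L)
  expect_lt(abs(si2$si - 1), 0.05)

  # zero denominator epoch becomes missing, not an error
  d3 <- rep(0.3, 10); t3 <- rep(0.2, 10)
  a3 <- rep(0.25, 10); b3 <- rep(0.25, 10)
  a3[3] <- 0; b3[3] <- 0
  si3 <- slowing_index(mk_relp(d3, t3, a3, b3))
  expect_equal(si3$n_used, 9L)

  expect_error(slowing_index(mk_relp(0.3, 0.2, 0.2, 0.2)), "3 epochs")
})

test_that("slope recovery works end-to-end on generated noise", {
  sl <- vapply(1:3, function(s) {
    x <- generate_colored_noise(300, 200, 1, 1, seed = 100 + s)
    spectral_slope(welch_psd(make_epochs(x, 200, rep("N2", 10))))$slope
  }, 0)
  expect_lt(abs(mean(sl) + 1), 0.15)
})

test_that("psd autoplot returns a ggplot", {
  p <- autoplot(psd_result(seq(0.5, 30, 0.5)^-2))
  expect_s3_class(p, "ggplot")
})
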