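# Spectral analysis: Welch PSD on 30-s epochs, log-log power-law slope,
# relative band power in the six classical bands, and the EEG/EOG slowing
# index with +/- 3 SD outlier masking.

PSD_GRID <- seq(0.5, 30, by = 0.5)

BAND_DEFS <- tibble(
  band = factor(c("slow", "delta", "theta", "alpha", "sigma", "beta"),
                levels = c("slow", "delta", "theta", "alpha", "sigma",
                           "beta")),
  low = c(0.5, 1, 4, 8, 12, 15),
  high = c(1, 4, 8, 12, 15, 30)
)

# Welch PSD of one vector: Hann windows of window_s seconds with overlap_s
# overlap, one-sided, in uV^2/Hz on the native fs/window grid.
welch_psd_vector <- function(x, fs, window_s = 4, overlap_s = 2) {
  nwin <- round(window_s * fs)
  hop <- nwin - round(overlap_s * fs)
  if (length(x) < nwin) abort("signal shorter than one Welch window")
  w <- hann_window(nwin)
  U <- sum(w^2)
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  nf <- floor(nwin / 2)
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1)]
    X <- fft(seg * w)
    acc <- acc + Mod(X[2:(nf + 1)])^2
  }
  p <- 2 * acc / (length(starts) * fs * U)
  list(freq = (1:nf) * fs / nwin, power = p)
}

# Collapse a native 0.25-Hz Welch grid to the 0.5-Hz output grid.
# Each output bin at frequency f is the mean of the native bins in
# (f - 0.25, f + 0.25], a centered two-bin average that preserves
# band-integrated power and keeps the heavily leakage-contaminated
# 0.25 Hz native bin out of the 0.5 Hz output bin (important for
# power-law slope fits on steep spectra).
collapse_to_grid <- function(freq, power) {
  vapply(PSD_GRID, function(f) {
    mean(power[freq > f - 0.25 + 1e-9 & freq <= f + 0.25 + 1e-9])
  }, 0)
}

#' Welch power spectral density per channel and stage
#'
#' For every epoch the PSD is estimated with 4-s Hann windows and 2-s
#' overlap (mean over windows), after per-epoch mean removal; epochs of a
#' stage are then averaged and reported on the fixed 0.5-30 Hz grid in
#' steps of 0.5 Hz (60 bins, microvolts squared per Hz).
#'
#' @param epochs an `epoched_signal` from [segment_epochs()].
#' @param stages stages to estimate (default: every stage present).
#' @param channels channel labels (default: all non-EMG channels).
#' @param window_s,overlap_s Welch window and overlap in seconds.
#'
#' @return A `psd_result` tibble with columns `channel`, `stage`, `freq`,
#'   `power`, `n_epochs`.
#' @export
welch_psd <- function(epochs, stages = NULL, channels = NULL,
                      window_s = 4, overlap_s = 2) {
  stages <- stages %||% unique(epochs$stage)
  channels <- channels %||% epochs$labels[epochs$classes != "EMG"]
  if (length(channels) == 0) channels <- epochs$labels
  out <- list()
  for (st in stages) {
    idx <- which(epochs$stage == st)
    if (length(idx) == 0) {
      abort(sprintf("no epochs of stage `%s`", st))
    }
    for (ch in channels) {
      jc <- match(ch, epochs$labels)
      acc <- numeric(length(PSD_GRID))
      for (i in idx) {
        x <- epochs$epochs[i, jc, ]
        x <- x - mean(x)
        wp <- welch_psd_vector(x, epochs$fs, window_s, overlap_s)
        acc <- acc + collapse_to_grid(wp$freq, wp$power)
      }
      out[[length(out) + 1]] <- tibble(
        channel = ch, stage = st, freq = PSD_GRID,
        power = acc / length(idx), n_epochs = length(idx))
    }
  }
  res <- bind_rows(out)
  class(res) <- c("psd_result", class(res))
  res
}

#' Construct a psd_result from explicit values
#'
#' Mainly useful to analyze analytically known spectra (e.g. exact power
#' laws) with [spectral_slope()] and [relative_band_power()].
#'
#' @param power numeric vector of length 60 on the 0.5-30 Hz grid.
#' @param channel,stage labels for the single spectrum.
#' @param n_epochs epoch count to record.
#' @return A `psd_result` tibble.
#' @export
psd_result <- function(power, channel = "C4-M1", stage = "N2",
                       n_epochs = 1) {
  stopifnot(length(power) == length(PSD_GRID), all(power >= 0))
  res <- tibble(channel = channel, stage = stage, freq = PSD_GRID,
                power = power, n_epochs = n_epochs)
  class(res) <- c("psd_result", class(res))
  res
}

#' Log-log power-law slope of a PSD
#'
#' Ordinary least squares of `log10(power)` on `log10(freq)` over the 60
#' grid bins, per channel and stage. Zero or negative power bins are
#' excluded with a warning (the fit needs positive power).
#'
#' @param psd a `psd_result` from [welch_psd()].
#' @return Tibble with `channel`, `stage`, `slope`, `intercept`, `r2`,
#'   `n_bins`.
#' @export
spectral_slope <- function(psd) {
  psd |>
    group_by(.data$channel, .data$stage) |>
    dplyr::reframe({
      ok <- .data$power > 0
      if (!all(ok)) {
        warn(sprintf("excluding %d non-positive power bin(s) from slope fit",
                     sum(!ok)))
      }
      lf <- log10(.data$freq[ok])
      lp <- log10(.data$power[ok])
      fit <- lm(lp ~ lf)
      r2 <- if (sum((lp - mean(lp))^2) == 0) 1 else
        1 - sum(fit$residuals^2) / sum((lp - mean(lp))^2)
      tibble(slope = unname(coef(fit)[2]),
             intercept = unname(coef(fit)[1]),
             r2 = r2, n_bins = sum(ok))
    })
}

band_label <- function(freq) {
  # half-open [low, high) except beta, which is [15, 30] inclusive, so the
  # six bands partition the 0.5-30 grid exactly
  cut(freq, breaks = c(BAND_DEFS$low, 30.000001), right = FALSE,
      labels = BAND_DEFS$band)
}

#' Absolute and relative band power
#'
#' Absolute band power is the sum of `power * delta_f` over grid bins in
#' the band (slow 0.5-1, delta 1-4, theta 4-8, alpha 8-12, sigma 12-15,
#' beta 15-30 Hz; bands are half-open on the right except beta so they
#' partition the grid). Relative power divides by total 0.5-30 Hz power,
#' so the six relative powers sum to one exactly.
#'
#' @param psd a `psd_result`.
#' @return Tibble with `channel`, `stage`, `band`, `abs_power`,
#'   `rel_power`.
#' @export
relative_band_power <- function(psd) {
  df <- 0.5
  out <- psd |>
    mutate(band = band_label(.data$freq)) |>
    group_by(.data$channel, .data$stage, .data$band) |>
    summarise(abs_power = sum(.data$power) * df, .groups = "drop_last") |>
    mutate(total = sum(.data$abs_power)) |>
    ungroup()
  if (any(out$total <= 0)) abort("zero total power in a channel/stage")
  out |>
    mutate(rel_power = .data$abs_power / .data$total) |>
    select(-"total")
}

#' Per-epoch relative band power
#'
#' Like [relative_band_power()] but per individual epoch, as needed by the
#' slowing index. Epochs with zero total power get missing relative powers.
#'
#' @param epochs an `epoched_signal`.
#' @param stages,channels subsets as in [welch_psd()].
#' @return Tibble with `epoch`, `channel`, `stage`, `band`, `rel_power`.
#' @export
epoch_band_powers <- function(epochs, stages = NULL, channels = NULL) {
  stages <- stages %||% unique(epochs$stage)
  channels <- channels %||% epochs$labels[epochs$classes != "EMG"]
  if (length(channels) == 0) channels <- epochs$labels
  out <- list()
  idx <- which(epochs$stage %in% stages)
  for (ch in channels) {
    jc <- match(ch, epochs$labels)
    for (i in idx) {
      x <- epochs$epochs[i, jc, ]
      x <- x - mean(x)
      wp <- welch_psd_vector(x, epochs$fs)
      p <- collapse_to_grid(wp$freq, wp$power)
      ab <- tapply(p * 0.5, band_label(PSD_GRID), sum)
      tot <- sum(ab)
      rel <- if (tot > 0) ab / tot else rep(NA_real_, length(ab))
      out[[length(out) + 1]] <- tibble(
        epoch = i, channel = ch, stage = epochs$stage[i],
        band = factor(names(ab), levels = levels(BAND_DEFS$band)),
        rel_power = as.numeric(rel))
    }
  }
  bind_rows(out)
}

# Outlier-masking function f: values beyond `k` sample SDs of the series
# mean are set to missing. A zero-variance series is left untouched.
mask_outliers <- function(v, k = 3) {
  m <- mean(v, na.rm = TRUE)
  s <- sd(v, na.rm = TRUE)
  if (is.na(s)) return(v)
  ifelse(!is.na(v) & abs(v - m) > k * s, NA_real_, v)
}

#' EEG/EOG slowing index
#'
#' The slowing index is the ratio of low-band (delta + theta) to high-band
#' (alpha + beta) relative power, computed per epoch and aggregated per
#' channel and stage. The outlier-masking function (set values beyond
#' +/- 3 sample SDs to missing) is applied at three nested levels: to each
#' relative band power across epochs, to the numerator and denominator
#' sums, and to the final ratio. Masked or degenerate (zero-denominator)
#' epochs propagate as missing; the reported index is the mean of the
#' surviving per-epoch ratios.
#'
#' @param epoch_relp output of [epoch_band_powers()].
#' @param outlier_sd masking threshold in SDs (3 by default).
#' @return Tibble with `channel`, `stage`, `si`, `n_epochs`, `n_used`.
#' @export
slowing_index <- function(epoch_relp, outlier_sd = 3) {
  wide <- tidyr::pivot_wider(epoch_relp, names_from = "band",
                             values_from = "rel_power")
  n_per_group <- wide |>
    dplyr::count(.data$channel, .data$stage)
  if (all(n_per_group$n < 3)) {
    abort("slowing index needs at least 3 epochs")
  }
  wide |>
    group_by(.data$channel, .data$stage) |>
    dplyr::reframe({
      n_ep <- length(.data$delta)
      if (n_ep < 3) {
        # SD undefined below 3 epochs: report missing for this group
        tibble(si = NA_real_, n_epochs = n_ep, n_used = 0L)
      } else {
        num <- mask_outliers(mask_outliers(.data$delta, outlier_sd) +
                               mask_outliers(.data$theta, outlier_sd),
                             outlier_sd)
        den <- mask_outliers(mask_outliers(.data$alpha, outlier_sd) +
                               mask_outliers(.data$beta, outlier_sd),
                             outlier_sd)
        ratio <- ifelse(!is.na(den) & den == 0, NA_real_, num / den)
        ratio <- mask_outliers(ratio, outlier_sd)
        tibble(si = if (all(is.na(ratio))) NA_real_ else
                 mean(ratio, na.rm = TRUE),
               n_epochs = length(ratio), n_used = sum(!is.na(ratio)))
      }
    })
}

#' Plot a PSD result on log-log axes
#'
#' @param object a `psd_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psd_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$freq, y = .data$power,
                               colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ .data$channel) +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz))) +
    ggplot2::theme_minimal()
}
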