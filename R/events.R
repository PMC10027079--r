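# Event-level analysis: wavelet spindle detection, criterion-based
# slow-oscillation detection, per-event feature tables, spindle/SO
# coupling, and time-locked averaging.

#' Spindle detector parameters
#'
#' @param fc wavelet center frequency in Hz (11 for slow spindles, 15 for
#'   fast spindles).
#' @param band_halfwidth_hz pre-filter half width (the signal is bandpassed
#'   `fc` +/- this before the wavelet).
#' @param cycles Morlet wavelet length in cycles at `fc` (bandwidth/time
#'   trade-off of the analytic Morlet).
#' @param smooth_win_s moving-average window applied to the wavelet
#'   magnitude, seconds.
#' @param core_thresh,core_dur_s core criterion: normalized magnitude at
#'   least `core_thresh` times the stage mean for at least `core_dur_s`.
#' @param ext_thresh,ext_dur_s extended criterion: at least `ext_thresh`
#'   times the stage mean for at least `ext_dur_s`; the extended run
#'   defines the event boundaries.
#' @param merge_gap_s events closer than this are merged.
#' @param max_dur_s events longer than this are discarded.
#' @return A `spindle_params` list.
#' @export
spindle_params <- function(fc = 11, band_halfwidth_hz = 2, cycles = 7,
                           smooth_win_s = 0.1, core_thresh = 4.5,
                           core_dur_s = 0.3, ext_thresh = 2,
                           ext_dur_s = 0.5, merge_gap_s = 0.5,
                           max_dur_s = 3) {
  stopifnot(fc > 0, core_thresh > ext_thresh, ext_thresh > 0,
            core_dur_s > 0, ext_dur_s > 0)
  structure(list(fc = fc, band_halfwidth_hz = band_halfwidth_hz,
                 cycles = cycles, smooth_win_s = smooth_win_s,
                 core_thresh = core_thresh, core_dur_s = core_dur_s,
                 ext_thresh = ext_thresh, ext_dur_s = ext_dur_s,
                 merge_gap_s = merge_gap_s, max_dur_s = max_dur_s),
            class = "spindle_params")
}

#' Slow-oscillation detector parameters
#'
#' Criteria evaluated on the 0.5-4 Hz forward-filtered (linear-phase FIR,
#' delay-compensated) signal: negative peak at most `neg_peak_max_uv`,
#' peak-to-peak at least `p2p_min_uv`, negative half-wave duration within
#' `neg_dur_s`, positive half-wave duration within `(0, pos_dur_max_s]`.
#'
#' @param band passband in Hz.
#' @param neg_peak_max_uv negative-peak criterion (microvolts, negative).
#' @param p2p_min_uv peak-to-peak criterion (microvolts).
#' @param neg_dur_s length-2 range for the negative half-wave (seconds).
#' @param pos_dur_max_s maximum positive half-wave duration (seconds).
#' @param transition_hz FIR transition width (sets the filter order).
#' @return An `so_params` list.
#' @export
so_params <- function(band = c(0.5, 4), neg_peak_max_uv = -40,
                      p2p_min_uv = 75, neg_dur_s = c(0.3, 1.5),
                      pos_dur_max_s = 1, transition_hz = 0.5) {
  stopifnot(neg_peak_max_uv < 0, p2p_min_uv > 0,
            neg_dur_s[1] < neg_dur_s[2], pos_dur_max_s > 0)
  structure(list(band = band, neg_peak_max_uv = neg_peak_max_uv,
                 p2p_min_uv = p2p_min_uv, neg_dur_s = neg_dur_s,
                 pos_dur_max_s = pos_dur_max_s,
                 transition_hz = transition_hz),
            class = "so_params")
}

# Pre-wavelet bandpass at fc +/- the half width. Linear-phase FIR with a
# 1 Hz transition: flat in the passband so in-band burst amplitudes are
# preserved (the Morlet wavelet supplies the frequency selectivity; this
# filter only suppresses out-of-band energy).
spindle_prefilter <- function(signal, fs, params) {
  fir_bandpass(signal, fs,
               params$fc - params$band_halfwidth_hz,
               params$fc + params$band_halfwidth_hz,
               transition_hz = 1)
}

# Magnitude of the complex Morlet wavelet transform at fc, normalized so a
# unit-amplitude tone at fc has magnitude ~1.
morlet_magnitude <- function(x, fs, fc, cycles = 7) {
  sigma_t <- cycles / (2 * pi * fc)
  half <- ceiling(4 * sigma_t * fs)
  tt <- (-half:half) / fs
  env <- exp(-tt^2 / (2 * sigma_t^2))
  psi <- env * exp(1i * 2 * pi * fc * tt)
  y <- fft_convolve_same(x, psi, center = half + 1)
  Mod(y) * 2 / sum(env)
}

# Linear-phase FIR bandpass with exact (integer) group-delay compensation.
fir_bandpass <- function(x, fs, low, high, transition_hz = 0.5) {
  ntaps <- ceiling(3.3 * fs / transition_hz)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  h <- signal::fir1(ntaps - 1, c(low, high) / (fs / 2), type = "pass")
  Re(fft_convolve_same(x, as.numeric(h), center = (ntaps + 1) / 2))
}

# Maximal runs of TRUE in a logical vector -> tibble(start, end) (sample
# indices, inclusive).
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start = starts[r$values], end = ends[r$values])
}

#' Detect sleep spindles with a Morlet-wavelet detector
#'
#' Pipeline: (1) bandpass `fc` +/- 2 Hz; (2) complex Morlet wavelet
#' magnitude at `fc`; (3) moving-average smoothing over 0.1 s; (4)
#' normalization by the mean smoothed magnitude over all epochs of the
#' normalization stages; (5) an event is a maximal run of at least 0.5 s
#' above 2x the mean that contains a sub-run of at least 0.3 s above 4.5x.
#' Event boundaries are those of the 2x run; the peak is at the magnitude
#' maximum. Events closer than `merge_gap_s` are merged, events longer
#' than `max_dur_s` discarded, and only events whose peak falls in a
#' target-stage epoch are kept.
#'
#' @param signal single-channel numeric vector (microvolts).
#' @param fs sampling rate in Hz; must be at least `2 * (fc + 2)`.
#' @param hypnogram 30-s stage labels covering the signal.
#' @param params a [spindle_params()] object.
#' @param norm_stages stages over which the normalization mean is taken.
#' @param target_stages stages in which events are reported.
#'
#' @return Tibble of events: `kind`, `onset_s`, `offset_s`, `peak_s`,
#'   `peak_norm` (peak normalized magnitude), `dur_s`.
#' @export
detect_spindles <- function(signal, fs, hypnogram,
                            params = spindle_params(),
                            norm_stages = c("N2", "N3"),
                            target_stages = c("N2", "N3")) {
  if (fs < 2 * (params$fc + params$band_halfwidth_hz)) {
    abort("sampling rate too low for the spindle band")
  }
  assert_stages(hypnogram)
  mask_norm <- stage_sample_mask(length(signal), fs, hypnogram, norm_stages)
  if (!any(mask_norm)) abort("no epochs of the normalization stages")
  mask_target <- stage_sample_mask(length(signal), fs, hypnogram,
                                   target_stages)

  bp <- spindle_prefilter(signal, fs, params)
  mag <- morlet_magnitude(bp, fs, params$fc, params$cycles)
  sm <- moving_average(mag, round(params$smooth_win_s * fs))
  norm <- sm / mean(sm[mask_norm])

  ext_runs <- logical_runs(norm >= params$ext_thresh)
  min_ext <- round(params$ext_dur_s * fs)
  min_core <- round(params$core_dur_s * fs)
  ev <- list()
  for (k in seq_len(nrow(ext_runs))) {
    s0 <- ext_runs$start[k]; s1 <- ext_runs$end[k]
    if (s1 - s0 + 1 < min_ext) next
    core <- logical_runs(norm[s0:s1] >= params$core_thresh)
    if (nrow(core) == 0 || max(core$end - core$start + 1) < min_core) next
    pk <- s0 - 1 + which.max(norm[s0:s1])
    ev[[length(ev) + 1]] <- tibble(
      onset_s = (s0 - 1) / fs, offset_s = s1 / fs,
      peak_s = (pk - 1) / fs, peak_norm = norm[pk])
  }
  kind <- if (params$fc < 13) "spindle_slow" else "spindle_fast"
  if (length(ev) == 0) {
    return(tibble(kind = character(), onset_s = numeric(),
                  offset_s = numeric(), peak_s = numeric(),
                  peak_norm = numeric(), dur_s = numeric()))
  }
  ev <- bind_rows(ev)

  # merge events separated by less than merge_gap_s
  merged <- list()
  cur <- ev[1, ]
  for (k in seq_len(nrow(ev))[-1]) {
    if (ev$onset_s[k] - cur$offset_s < params$merge_gap_s) {
      cur$offset_s <- max(cur$offset_s, ev$offset_s[k])
      if (ev$peak_norm[k] > cur$peak_norm) {
        cur$peak_norm <- ev$peak_norm[k]
        cur$peak_s <- ev$peak_s[k]
      }
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- ev[k, ]
    }
  }
  merged[[length(merged) + 1]] <- cur
  ev <- bind_rows(merged) |>
    mutate(kind = kind, dur_s = .data$offset_s - .data$onset_s) |>
    filter(.data$dur_s <= params$max_dur_s) |>
    filter(mask_target[pmin(floor(.data$peak_s * fs) + 1,
                            length(mask_target))]) |>
    select("kind", "onset_s", "offset_s", "peak_s", "peak_norm", "dur_s")
  ev
}

#' Detect slow oscillations by amplitude/duration criteria
#'
#' The signal is bandpassed 0.5-4 Hz with a linear-phase FIR filter
#' (delay-compensated). A candidate is a negative half-wave (between a
#' downward and the next upward zero crossing) immediately followed by a
#' positive half-wave; it is accepted iff all four criteria hold: negative
#' peak <= -40 uV, peak-to-peak >= 75 uV, negative duration in [0.3, 1.5] s
#' and positive duration in (0, 1] s. The event spans both half-waves with
#' the peak at the negative peak. Only events whose negative peak falls in
#' a target-stage epoch are kept.
#'
#' @param signal single-channel numeric vector (microvolts).
#' @param fs sampling rate in Hz (`>= 100`).
#' @param hypnogram 30-s stage labels covering the signal.
#' @param params an [so_params()] object.
#' @param target_stages stages in which events are reported.
#'
#' @return Tibble of events: `kind`, `onset_s`, `offset_s`, `peak_s`,
#'   `neg_peak_uv`, `pos_peak_uv`, `p2p_uv`, `neg_dur_s`, `pos_dur_s`,
#'   `dur_s`.
#' @export
detect_slow_oscillations <- function(signal, fs, hypnogram,
                                     params = so_params(),
                                     target_stages = c("N2", "N3")) {
  if (fs < 100) abort("sampling rate must be at least 100 Hz")
  assert_stages(hypnogram)
  mask_target <- stage_sample_mask(length(signal), fs, hypnogram,
                                   target_stages)
  filt <- fir_bandpass(signal, fs, params$band[1], params$band[2],
                       params$transition_hz)
  pos <- filt >= 0
  n <- length(filt)
  down <- which(pos[-n] & !pos[-1])     # last non-negative sample index
  up <- which(!pos[-n] & pos[-1])
  if (length(down) == 0 || length(up) == 0) {
    abort("no zero crossings in the filtered signal")
  }
  out <- list()
  for (d in down) {
    u <- up[up > d][1]
    if (is.na(u)) break
    d2 <- down[down > u][1]
    if (is.na(d2)) break
    neg_idx <- (d + 1):u
    pos_idx <- (u + 1):d2
    neg_dur <- (u - d) / fs
    pos_dur <- (d2 - u) / fs
    neg_peak <- min(filt[neg_idx])
    pos_peak <- max(filt[pos_idx])
    ok <- neg_peak <= params$neg_peak_max_uv &&
      (pos_peak - neg_peak) >= params$p2p_min_uv &&
      neg_dur >= params$neg_dur_s[1] && neg_dur <= params$neg_dur_s[2] &&
      pos_dur > 0 && pos_dur <= params$pos_dur_max_s
    if (!ok) next
    pk <- d + which.min(filt[neg_idx])
    if (!mask_target[pk]) next
    out[[length(out) + 1]] <- tibble(
      kind = "so", onset_s = d / fs, offset_s = d2 / fs,
      peak_s = (pk - 1) / fs, neg_peak_uv = neg_peak,
      pos_peak_uv = pos_peak, p2p_uv = pos_peak - neg_peak,
      neg_dur_s = neg_dur, pos_dur_s = pos_dur,
      dur_s = (d2 - d) / fs)
  }
  if (length(out) == 0) {
    return(tibble(kind = character(), onset_s = numeric(),
                  offset_s = numeric(), peak_s = numeric(),
                  neg_peak_uv = numeric(), pos_peak_uv = numeric(),
                  p2p_uv = numeric(), neg_dur_s = numeric(),
                  pos_dur_s = numeric(), dur_s = numeric()))
  }
  bind_rows(out)
}

#' Flag spindles coupled to slow oscillations
#'
#' A spindle is coupled iff its `[onset_s, offset_s)` interval intersects
#' any SO's interval; a spindle overlapping several SOs counts once.
#'
#' @param spindles,sos event tibbles from the detectors (same channel and
#'   night).
#' @return The spindle tibble with a logical `coupled` column; the total
#'   count is `sum(out$coupled)`.
#' @export
couple_overlap <- function(spindles, sos) {
  if (nrow(spindles) == 0) {
    return(mutate(spindles, coupled = logical(0)))
  }
  coupled <- vapply(seq_len(nrow(spindles)), function(i) {
    any(spindles$onset_s[i] < sos$offset_s &
          sos$onset_s < spindles$offset_s[i])
  }, TRUE)
  mutate(spindles, coupled = coupled)
}

# minutes of target stage present in both the hypnogram and the signal
stage_minutes <- function(signal, fs, hypnogram, stages) {
  n_ep <- min(length(hypnogram), floor(length(signal) / (30 * fs)))
  sum(hypnogram[seq_len(n_ep)] %in% stages) * 0.5
}

#' Spindle feature table
#'
#' One-row summary of a detected spindle set: DENS (events/min of target
#' stage), DUR (mean duration, s), FRQ (mean within-event zero-crossing
#' frequency, Hz), FFT (mean within-event spectral peak frequency, Hz),
#' FWHM (mean full width at half maximum of the smoothed wavelet magnitude
#' around the peak, s), N / N01 / N02 / N2 (event counts: all, extended
#' criterion >= 0.5 s, core-only >= 0.3 s, peak in stage N2), NOSC (mean
#' oscillation cycles per event) and CO (number of SO-coupled spindles,
#' when `sos` is given).
#'
#' @param spindles events from [detect_spindles()].
#' @param signal,fs,hypnogram the channel the events came from.
#' @param params the [spindle_params()] used for detection.
#' @param sos optional SO events for the coupling count.
#' @param target_stages stage set for the density denominator.
#' @return One-row tibble.
#' @export
spindle_features <- function(spindles, signal, fs, hypnogram,
                             params = spindle_params(), sos = NULL,
                             target_stages = c("N2", "N3")) {
  mins <- stage_minutes(signal, fs, hypnogram, target_stages)
  if (nrow(spindles) == 0) {
    return(tibble(DENS = 0, DUR = NA_real_, FRQ = NA_real_,
                  FFT = NA_real_, FWHM = NA_real_, N = 0L, N01 = 0L,
                  N02 = 0L, N2 = 0L, NOSC = NA_real_, CO = NA_integer_))
  }
  bp <- spindle_prefilter(signal, fs, params)
  mag <- moving_average(morlet_magnitude(bp, fs, params$fc, params$cycles),
                        round(params$smooth_win_s * fs))
  per <- purrr::map_dfr(seq_len(nrow(spindles)), function(i) {
    i0 <- floor(spindles$onset_s[i] * fs) + 1
    i1 <- min(ceiling(spindles$offset_s[i] * fs), length(signal))
    seg <- bp[i0:i1]
    nzc <- sum(diff(sign(seg)) != 0)
    dur <- spindles$offset_s[i] - spindles$onset_s[i]
    frq <- nzc / 2 / dur
    # within-event spectral peak
    spec <- Mod(fft(seg * hann_window(length(seg))))^2
    ff <- (seq_along(spec) - 1) * fs / length(spec)
    inband <- ff >= params$fc - params$band_halfwidth_hz - 1 &
      ff <= params$fc + params$band_halfwidth_hz + 1
    fft_peak <- if (any(inband)) ff[inband][which.max(spec[inband])]
      else NA_real_
    # FWHM on the smoothed magnitude around the event peak
    pk <- floor(spindles$peak_s[i] * fs) + 1
    half <- mag[pk] / 2
    lo <- pk; while (lo > 1 && mag[lo - 1] >= half) lo <- lo - 1
    hi <- pk; while (hi < length(mag) && mag[hi + 1] >= half) hi <- hi + 1
    tibble(frq = frq, fft = fft_peak, fwhm = (hi - lo + 1) / fs,
           nosc = nzc / 2)
  })
  n_ep <- min(length(hypnogram), floor(length(signal) / (30 * fs)))
  pk_ep <- pmin(floor(spindles$peak_s / 30) + 1, n_ep)
  co <- if (!is.null(sos)) sum(couple_overlap(spindles, sos)$coupled)
    else NA_integer_
  tibble(
    DENS = nrow(spindles) / mins,
    DUR = mean(spindles$dur_s),
    FRQ = mean(per$frq),
    FFT = mean(per$fft, na.rm = TRUE),
    FWHM = mean(per$fwhm),
    N = nrow(spindles),
    N01 = sum(spindles$dur_s >= params$ext_dur_s),
    N02 = sum(spindles$dur_s >= params$core_dur_s),
    N2 = sum(hypnogram[pk_ep] == "N2"),
    NOSC = mean(per$nosc),
    CO = as.integer(co)
  )
}

#' Slow-oscillation feature table
#'
#' One-row summary of a detected SO set: Num, DUR (median duration),
#' NEG_AMP / POS_AMP (median peak amplitudes, uV), NEG_DUR / POS_DUR
#' (median half-wave durations, s), P2P (median peak-to-peak, uV), RATE
#' (events/min of target stage), SLOPE_N1 / SLOPE_N2 (median slope of the
#' filtered signal from the preceding zero crossing to the negative peak,
#' and from the negative peak to the following zero crossing, uV/s),
#' TH_NEG (the negative-peak threshold used) and TRANS (number of coupled
#' spindles whose peak falls in an SO positive half-wave, when `spindles`
#' is given).
#'
#' @param sos events from [detect_slow_oscillations()].
#' @param signal,fs,hypnogram the channel the events came from.
#' @param params the [so_params()] used for detection.
#' @param spindles optional spindle events for the TRANS count.
#' @param target_stages stage set for the rate denominator.
#' @return One-row tibble.
#' @export
so_features <- function(sos, signal, fs, hypnogram, params = so_params(),
                        spindles = NULL, target_stages = c("N2", "N3")) {
  mins <- stage_minutes(signal, fs, hypnogram, target_stages)
  if (nrow(sos) == 0) {
    return(tibble(Num = 0L, DUR = NA_real_, NEG_AMP = NA_real_,
                  POS_AMP = NA_real_, NEG_DUR = NA_real_,
                  POS_DUR = NA_real_, P2P = NA_real_, RATE = 0,
                  SLOPE_N1 = NA_real_, SLOPE_N2 = NA_real_,
                  TH_NEG = params$neg_peak_max_uv, TRANS = NA_integer_))
  }
  # slopes need the filtered trace
  filt <- fir_bandpass(signal, fs, params$band[1], params$band[2],
                       params$transition_hz)
  slopes <- purrr::map_dfr(seq_len(nrow(sos)), function(i) {
    t_on <- sos$onset_s[i]
    t_pk <- sos$peak_s[i]
    t_zc <- sos$onset_s[i] + sos$neg_dur_s[i]  # up crossing
    pk_val <- sos$neg_peak_uv[i]
    tibble(n1 = (pk_val - 0) / (t_pk - t_on),
           n2 = (0 - pk_val) / (t_zc - t_pk))
  })
  trans <- NA_integer_
  if (!is.null(spindles) && nrow(spindles) > 0) {
    trans <- 0L
    for (i in seq_len(nrow(spindles))) {
      pk <- spindles$peak_s[i]
      in_pos <- any(pk >= sos$onset_s + sos$neg_dur_s & pk < sos$offset_s)
      if (in_pos) trans <- trans + 1L
    }
  }
  tibble(
    Num = nrow(sos),
    DUR = median(sos$dur_s),
    NEG_AMP = median(sos$neg_peak_uv),
    POS_AMP = median(sos$pos_peak_uv),
    NEG_DUR = median(sos$neg_dur_s),
    POS_DUR = median(sos$pos_dur_s),
    P2P = median(sos$p2p_uv),
    RATE = nrow(sos) / mins,
    SLOPE_N1 = median(slopes$n1),
    SLOPE_N2 = median(slopes$n2),
    TH_NEG = params$neg_peak_max_uv,
    TRANS = trans
  )
}

#' Per-event feature table for either detector
#'
#' Dispatches on the `kind` column: spindle events go to
#' [spindle_features()], SO events to [so_features()].
#'
#' @param events a detector output tibble.
#' @param signal,fs,hypnogram the channel the events came from.
#' @param ... forwarded to the specific feature function.
#' @return One-row tibble of features.
#' @export
event_features <- function(events, signal, fs, hypnogram, ...) {
  if (nrow(events) > 0 && all(events$kind == "so")) {
    so_features(events, signal, fs, hypnogram, ...)
  } else {
    spindle_features(events, signal, fs, hypnogram, ...)
  }
}

#' Time-locked average around event anchors
#'
#' Averages signal segments of `2 * half_window_s` centered on each
#' event's anchor time (`peak_s` for spindles and SO negative peaks).
#' Events whose window exceeds the recording bounds are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @param events event tibble with a `peak_s` column.
#' @param half_window_s half window in seconds.
#' @return Tibble with `time_s` (relative to the anchor) and `mean_uv`;
#'   attributes `n_events`, `n_excluded`.
#' @export
time_locked_average <- function(signal, fs, events, half_window_s = 1) {
  if (nrow(events) == 0) abort("no events to average")
  hw <- round(half_window_s * fs)
  centers <- floor(events$peak_s * fs) + 1
  ok <- centers - hw >= 1 & centers + hw <= length(signal)
  if (!any(ok)) abort("no event has a full window inside the recording")
  seg <- vapply(centers[ok], function(c0) signal[(c0 - hw):(c0 + hw)],
                numeric(2 * hw + 1))
  out <- tibble(time_s = (-hw:hw) / fs, mean_uv = rowMeans(seg))
  attr(out, "n_events") <- sum(ok)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Plot a time-locked average waveform
#'
#' @param avg output of [time_locked_average()].
#' @return A ggplot object.
#' @export
plot_time_locked <- function(avg) {
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$time_s, y = .data$mean_uv)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time from anchor (s)", y = expression(mu * V)) +
    ggplot2::theme_minimal()
}
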