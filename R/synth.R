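# Synthetic sleep-night generator: hypnograms, stage-dependent 1/f^alpha
# signals, ground-truth spindle / slow-oscillation events, scorer noise and
# paired-device measurements. Everything is driven by one integer seed,
# split deterministically into named sub-streams.

#' Stage profile for synthetic signal generation
#'
#' Describes the background EEG of one sleep stage: a power-law spectral
#' exponent `alpha` (PSD proportional to `f^-alpha`), an RMS amplitude,
#' optional narrowband oscillations riding on the background, and event
#' rates for spindles and slow oscillations.
#'
#' @param stage stage label (`W`, `N1`, `N2`, `N3`, `REM`).
#' @param alpha spectral exponent, `>= 0`.
#' @param rms_uv background RMS amplitude in microvolts, `> 0`.
#' @param osc_bands list of `c(center_hz, bandwidth_hz, rel_amplitude)`
#'   oscillation descriptors (e.g. posterior alpha in wake).
#' @param spindle_rate,so_rate expected events per minute (`>= 0`).
#' @param spindle_amp_uv peak amplitude of injected spindles (microvolts).
#' @param so_neg_amp_uv,so_pos_amp_uv slow-oscillation half-wave
#'   amplitudes in microvolts (negative value for the down state).
#'
#' @return A `stage_profile` list.
#' @export
stage_profile <- function(stage, alpha, rms_uv, osc_bands = list(),
                          spindle_rate = 0, so_rate = 0,
                          spindle_amp_uv = 20,
                          so_neg_amp_uv = -80, so_pos_amp_uv = 50) {
  stopifnot(stage %in% SLEEP_STAGES, alpha >= 0, rms_uv > 0,
            spindle_rate >= 0, so_rate >= 0)
  structure(list(stage = stage, alpha = alpha, rms_uv = rms_uv,
                 osc_bands = osc_bands, spindle_rate = spindle_rate,
                 so_rate = so_rate, spindle_amp_uv = spindle_amp_uv,
                 so_neg_amp_uv = so_neg_amp_uv,
                 so_pos_amp_uv = so_pos_amp_uv),
            class = "stage_profile")
}

#' Default stage profiles
#'
#' Plausible per-stage parameters for healthy adult sleep EEG: the
#' aperiodic slope steepens from wake through N3 and relaxes in REM,
#' amplitude grows with NREM depth, wake carries a posterior-alpha
#' oscillation, spindles occur in N2/N3 and slow oscillations in N3.
#' These defaults define the simulated study conditions; see the methods
#' vignette for the rationale behind each number.
#'
#' @return Named list of [stage_profile()] objects, one per stage.
#' @export
default_stage_profiles <- function() {
  list(
    W   = stage_profile("W",   alpha = 1.2, rms_uv = 15,
                        osc_bands = list(c(10, 2, 0.6))),
    N1  = stage_profile("N1",  alpha = 1.5, rms_uv = 20,
                        osc_bands = list(c(5, 2, 0.3))),
    N2  = stage_profile("N2",  alpha = 2.0, rms_uv = 30,
                        spindle_rate = 3, spindle_amp_uv = 25),
    N3  = stage_profile("N3",  alpha = 2.6, rms_uv = 50,
                        spindle_rate = 1, so_rate = 5,
                        spindle_amp_uv = 25),
    REM = stage_profile("REM", alpha = 1.6, rms_uv = 18,
                        osc_bands = list(c(6, 2, 0.25)))
  )
}

#' Default 8-channel polysomnography montage
#'
#' Five EEG derivations, two EOG derivations and one chin EMG channel,
#' the standard reduced montage for sleep staging.
#'
#' @return Tibble with columns `label` and `class`.
#' @export
default_montage <- function() {
  tibble(
    label = c("F4-M1", "C4-M1", "P4-M1", "T4-M1", "O2-M1",
              "E1-M2", "E2-M2", "EMG"),
    class = c(rep("EEG", 5), "EOG", "EOG", "EMG")
  )
}

#' Generate a synthetic hypnogram
#'
#' Builds a night of 30-s stage labels whose realized stage fractions match
#' the requested proportions (exactly, up to integer rounding) while the
#' stages are laid out in alternating NREM/REM cycles of roughly
#' `cycle_period_epochs`, starting from wake. The layout is a deterministic
#' cycle template with seeded jitter of the per-cycle allocations, not a
#' Markov chain, so realized proportions are controlled exactly.
#'
#' @param n_epochs number of 30-s epochs (`>= 1`).
#' @param proportions named fractions over `W`, `N1`, `N2`, `N3`, `REM`;
#'   must sum to 1. Defaults follow healthy-adult guidance (about 50% N2,
#'   20% N3, 25% REM, remainder wake/N1).
#' @param cycle_period_epochs approximate cycle length in epochs
#'   (180 epochs = 90 min).
#' @param seed integer seed.
#'
#' @return Character vector of length `n_epochs` with stage labels.
#' @export
#' @examples
#' h <- generate_hypnogram(960, seed = 1)
#' table(h) / length(h)
generate_hypnogram <- function(n_epochs,
                               proportions = c(W = 0.03, N1 = 0.02,
                                               N2 = 0.50, N3 = 0.20,
                                               REM = 0.25),
                               cycle_period_epochs = 180, seed = 1) {
  if (n_epochs < 1) abort("`n_epochs` must be >= 1")
  assert_stages(names(proportions), "proportions")
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("`proportions` must sum to 1")
  }
  full <- stats::setNames(rep(0, 5), SLEEP_STAGES)
  full[names(proportions)] <- proportions

  # largest-remainder rounding to exact epoch counts
  raw <- full * n_epochs
  counts <- floor(raw)
  rem <- n_epochs - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }

  with_seed(seed, {
    lead_w <- if (counts["W"] > 0) ceiling(counts["W"] / 2) else 0
    counts["W"] <- counts["W"] - lead_w
    body_n <- n_epochs - lead_w
    n_cycles <- max(1L, round(body_n / cycle_period_epochs))

    # per-cycle share of each stage: proportional with jittered weights,
    # largest-remainder so totals stay exact
    wts <- 1 + 0.15 * runif(n_cycles)
    wts <- wts / sum(wts)
    alloc <- sapply(SLEEP_STAGES, function(s) {
      raw_c <- counts[s] * wts
      a <- floor(raw_c)
      extra <- counts[s] - sum(a)
      if (extra > 0) {
        ord <- order(raw_c - a, decreasing = TRUE)
        a[ord[seq_len(extra)]] <- a[ord[seq_len(extra)]] + 1
      }
      a
    })
    alloc <- matrix(alloc, nrow = n_cycles,
                    dimnames = list(NULL, SLEEP_STAGES))

    out <- rep("W", lead_w)
    for (c in seq_len(n_cycles)) {
      n2a <- ceiling(alloc[c, "N2"] * 0.6)
      cyc <- c(rep("N1", alloc[c, "N1"]),
               rep("N2", n2a),
               rep("N3", alloc[c, "N3"]),
               rep("N2", alloc[c, "N2"] - n2a),
               rep("REM", alloc[c, "REM"]),
               rep("W", alloc[c, "W"]))
      out <- c(out, cyc)
    }
    stopifnot(length(out) == n_epochs)
    out
  })
}

#' Generate power-law (1/f^alpha) colored noise
#'
#' White Gaussian noise is shaped in the frequency domain: the FFT
#' amplitudes are multiplied by `f^(-alpha/2)` so the resulting PSD is
#' proportional to `f^-alpha`, then the series is rescaled to the exact
#' target RMS. The DC component is zeroed.
#'
#' @param duration_s duration in seconds.
#' @param fs sampling rate in Hz.
#' @param alpha spectral exponent (`>= 0`; 0 gives white noise).
#' @param rms_uv target RMS amplitude in microvolts.
#' @param seed integer seed.
#'
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
generate_colored_noise <- function(duration_s, fs, alpha, rms_uv = 1,
                                   seed = 1) {
  if (duration_s <= 0 || fs <= 0) abort("duration and fs must be positive")
  n <- round(duration_s * fs)
  if (n < 2) abort("duration_s * fs must be at least 2")
  if (alpha < 0) abort("`alpha` must be >= 0")
  with_seed(seed, {
    w <- rnorm(n)
    X <- fft(w)
    f <- c(0, seq_len(n - 1))
    f <- pmin(f, n - f) * fs / n      # two-sided frequency magnitudes
    shape <- c(0, f[-1] ^ (-alpha / 2))
    x <- Re(fft(X * shape, inverse = TRUE) / n)
    x * rms_uv / sqrt(mean(x^2))
  })
}

#' Ground-truth event table constructor
#'
#' Events are half-open intervals `[onset_s, offset_s)` on a named channel.
#' Spindles carry a frequency and peak amplitude; slow oscillations carry
#' negative/positive half-wave amplitudes and the negative half-wave
#' duration (the positive half-wave fills the rest of the span).
#'
#' @param channel,kind,onset_s,offset_s vectors of equal length; `kind` is
#'   one of `"spindle_slow"`, `"spindle_fast"`, `"so"`.
#' @param freq_hz,amp_uv spindle frequency (Hz) and peak amplitude.
#' @param neg_amp_uv,pos_amp_uv,neg_dur_s slow-oscillation parameters.
#'
#' @return Tibble sorted by channel then onset.
#' @export
ground_truth_events <- function(channel = character(), kind = character(),
                                onset_s = numeric(), offset_s = numeric(),
                                freq_hz = NA_real_, amp_uv = NA_real_,
                                neg_amp_uv = NA_real_, pos_amp_uv = NA_real_,
                                neg_dur_s = NA_real_) {
  ev <- tibble(channel = channel, kind = kind, onset_s = onset_s,
               offset_s = offset_s, freq_hz = freq_hz, amp_uv = amp_uv,
               neg_amp_uv = neg_amp_uv, pos_amp_uv = pos_amp_uv,
               neg_dur_s = neg_dur_s)
  if (any(ev$offset_s <= ev$onset_s)) abort("offset_s must exceed onset_s")
  dplyr::arrange(ev, .data$channel, .data$onset_s)
}

#' Inject ground-truth events into a single-channel signal
#'
#' Spindle events add a Hann-windowed sinusoid at `freq_hz` spanning
#' `[onset_s, offset_s)`; slow-oscillation events add one biphasic wave
#' (a negative half-sine of duration `neg_dur_s` reaching `neg_amp_uv`,
#' immediately followed by a positive half-sine reaching `pos_amp_uv`).
#' Samples outside all event windows are unchanged.
#'
#' @param signal numeric vector (microvolts).
#' @param fs sampling rate in Hz.
#' @param events a [ground_truth_events()] tibble (the `channel` column is
#'   ignored here).
#'
#' @return The signal with events added.
#' @export
inject_events <- function(signal, fs, events) {
  if (nrow(events) == 0) return(signal)
  dur_s <- length(signal) / fs
  if (any(events$onset_s < 0) || any(events$offset_s > dur_s + 1e-9)) {
    abort("event exceeds signal bounds")
  }
  out <- signal
  for (i in seq_len(nrow(events))) {
    i0 <- floor(events$onset_s[i] * fs) + 1
    i1 <- ceiling(events$offset_s[i] * fs)
    idx <- i0:min(i1, length(signal))
    tt <- (idx - 1) / fs - events$onset_s[i]
    dur <- events$offset_s[i] - events$onset_s[i]
    if (events$kind[i] %in% c("spindle_slow", "spindle_fast")) {
      env <- 0.5 * (1 - cos(2 * pi * tt / dur))
      out[idx] <- out[idx] +
        events$amp_uv[i] * env * sin(2 * pi * events$freq_hz[i] * tt)
    } else if (events$kind[i] == "so") {
      d1 <- events$neg_dur_s[i]
      if (is.na(d1)) d1 <- 0.6 * dur
      d2 <- dur - d1
      wave <- numeric(length(tt))
      neg <- tt < d1
      wave[neg] <- events$neg_amp_uv[i] * sin(pi * tt[neg] / d1)
      wave[!neg] <- events$pos_amp_uv[i] * sin(pi * (tt[!neg] - d1) / d2)
      out[idx] <- out[idx] + wave
    } else {
      abort(sprintf("unknown event kind `%s`", events$kind[i]))
    }
  }
  out
}

#' Generate a full synthetic recording from a hypnogram
#'
#' Each 30-s epoch of each channel is drawn from its stage's profile
#' (power-law background plus oscillation bands); spindles are injected in
#' N2/N3 epochs and slow oscillations in N3 epochs (configurable) of EEG
#' channels, and the exhaustive ground-truth event list is returned.
#'
#' @param hypnogram character vector of stage labels.
#' @param profiles named list of [stage_profile()]s covering every stage
#'   present.
#' @param montage tibble with `label` and `class` columns
#'   ([default_montage()]).
#' @param fs sampling rate in Hz (500 by default).
#' @param seed integer seed.
#' @param spindle_stages,so_stages stages eligible for event injection.
#'
#' @return List with elements `recording` (a [new_recording()]) and
#'   `events` (a [ground_truth_events()] tibble).
#' @export
generate_recording <- function(hypnogram, profiles = default_stage_profiles(),
                               montage = default_montage(), fs = 500,
                               seed = 1,
                               spindle_stages = c("N2", "N3"),
                               so_stages = "N3") {
  assert_stages(hypnogram)
  missing_p <- setdiff(unique(hypnogram), names(profiles))
  if (length(missing_p) > 0) {
    abort(sprintf("missing profile for stage(s): %s",
                  paste(missing_p, collapse = ", ")))
  }
  spe <- round(30 * fs)
  n_ep <- length(hypnogram)
  data <- matrix(0, nrow = n_ep * spe, ncol = nrow(montage))
  all_events <- list()

  for (j in seq_len(nrow(montage))) {
    lab <- montage$label[j]
    cls <- montage$class[j]
    ch_seed <- derive_seed(seed, paste0("chan:", lab))
    x <- numeric(n_ep * spe)
    for (i in seq_len(n_ep)) {
      prof <- profiles[[hypnogram[i]]]
      ep_seed <- derive_seed(ch_seed, paste0("epoch:", i))
      if (cls == "EMG") {
        seg <- generate_colored_noise(30, fs, 0.3, prof$rms_uv * 0.3,
                                      seed = ep_seed)
      } else {
        seg <- generate_colored_noise(30, fs, prof$alpha, prof$rms_uv,
                                      seed = ep_seed)
        if (length(prof$osc_bands) > 0) {
          seg <- seg + with_seed(derive_seed(ep_seed, "osc"), {
            osc <- numeric(spe)
            tt <- (0:(spe - 1)) / fs
            for (b in prof$osc_bands) {
              fo <- b[1] + runif(1, -b[2] / 2, b[2] / 2)
              osc <- osc + b[3] * prof$rms_uv * sqrt(2) *
                sin(2 * pi * fo * tt + runif(1, 0, 2 * pi))
            }
            osc
          })
        }
      }
      x[((i - 1) * spe + 1):(i * spe)] <- seg
    }

    # ground-truth events on EEG channels only
    if (cls == "EEG") {
      ev <- with_seed(derive_seed(ch_seed, "events"), {
        rows <- list()
        for (i in seq_len(n_ep)) {
          prof <- profiles[[hypnogram[i]]]
          t0 <- (i - 1) * 30
          if (hypnogram[i] %in% spindle_stages && prof$spindle_rate > 0) {
            k <- rpois(1, prof$spindle_rate * 0.5)
            if (k > 0) {
              dur <- runif(k, 0.6, 1.4)
              onset <- t0 + runif(k, 0.5, 30 - max(dur) - 0.5)
              fast <- runif(k) < 0.5
              rows[[length(rows) + 1]] <- tibble(
                channel = lab,
                kind = ifelse(fast, "spindle_fast", "spindle_slow"),
                onset_s = onset, offset_s = onset + dur,
                freq_hz = ifelse(fast, runif(k, 14, 16), runif(k, 10, 12)),
                amp_uv = prof$spindle_amp_uv * runif(k, 0.8, 1.2),
                neg_amp_uv = NA_real_, pos_amp_uv = NA_real_,
                neg_dur_s = NA_real_)
            }
          }
          if (hypnogram[i] %in% so_stages && prof$so_rate > 0) {
            k <- rpois(1, prof$so_rate * 0.5)
            if (k > 0) {
              d1 <- runif(k, 0.5, 1.0)
              d2 <- runif(k, 0.3, 0.8)
              onset <- t0 + runif(k, 0.5, 30 - max(d1 + d2) - 0.5)
              rows[[length(rows) + 1]] <- tibble(
                channel = lab, kind = "so",
                onset_s = onset, offset_s = onset + d1 + d2,
                freq_hz = NA_real_, amp_uv = NA_real_,
                neg_amp_uv = prof$so_neg_amp_uv * runif(k, 0.8, 1.2),
                pos_amp_uv = prof$so_pos_amp_uv * runif(k, 0.8, 1.2),
                neg_dur_s = d1)
            }
          }
        }
        if (length(rows) == 0) {
          ground_truth_events()
        } else {
          ev <- dplyr::arrange(bind_rows(rows), .data$onset_s)
          # drop same-kind-class overlaps (spindle vs spindle, so vs so)
          drop_overlaps <- function(e) {
            if (nrow(e) < 2) return(e)
            keep <- rep(TRUE, nrow(e))
            last_off <- e$offset_s[1]
            for (r in 2:nrow(e)) {
              if (e$onset_s[r] < last_off) keep[r] <- FALSE
              else last_off <- e$offset_s[r]
            }
            e[keep, ]
          }
          sp <- drop_overlaps(ev[ev$kind != "so", ])
          so <- drop_overlaps(ev[ev$kind == "so", ])
          dplyr::arrange(bind_rows(sp, so), .data$onset_s)
        }
      })
      if (nrow(ev) > 0) {
        x <- inject_events(x, fs, ev)
        all_events[[length(all_events) + 1]] <- ev
      }
    }
    data[, j] <- x
  }

  events <- if (length(all_events) > 0) {
    dplyr::arrange(bind_rows(all_events), .data$channel, .data$onset_s)
  } else {
    ground_truth_events()
  }
  list(recording = new_recording(data, fs, montage$label, montage$class),
       events = events)
}

#' Build a scorer confusion matrix
#'
#' Row-stochastic 5x5 matrix: row = true stage, column = assigned stage.
#' `accuracy` is placed on the diagonal and the remainder spread over
#' adjacent-in-depth stages (the typical pattern of human disagreement,
#' N1 being hardest).
#'
#' @param accuracy probability of assigning the true stage (0-1).
#' @return 5x5 matrix with rownames/colnames `W`, `N1`, `N2`, `N3`, `REM`.
#' @export
scorer_confusion <- function(accuracy = 0.85) {
  stopifnot(accuracy >= 0, accuracy <= 1)
  neighbors <- list(W = c("N1", "REM"), N1 = c("W", "N2", "REM"),
                    N2 = c("N1", "N3"), N3 = "N2", REM = c("N1", "W"))
  conf <- matrix(0, 5, 5, dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  for (s in SLEEP_STAGES) {
    conf[s, s] <- accuracy
    nb <- neighbors[[s]]
    conf[s, nb] <- (1 - accuracy) / length(nb)
  }
  conf
}

#' Simulate independent scorers from a true hypnogram
#'
#' Each scorer's label for each epoch is drawn independently from the
#' confusion-matrix row of the true stage.
#'
#' @param truth character vector of true stages.
#' @param confusion 5x5 row-stochastic matrix ([scorer_confusion()]).
#' @param n_scorers number of scorers (`>= 1`).
#' @param seed integer seed.
#'
#' @return List of `n_scorers` hypnograms.
#' @export
simulate_scorers <- function(truth, confusion, n_scorers = 3, seed = 1) {
  assert_stages(truth, "truth")
  if (n_scorers < 1) abort("`n_scorers` must be >= 1")
  if (!all(dim(confusion) == c(5, 5)) ||
      any(abs(rowSums(confusion) - 1) > 1e-12) || any(confusion < 0)) {
    abort("`confusion` must be a 5x5 row-stochastic matrix")
  }
  if (is.null(rownames(confusion))) {
    dimnames(confusion) <- list(SLEEP_STAGES, SLEEP_STAGES)
  }
  with_seed(seed, {
    lapply(seq_len(n_scorers), function(s) {
      vapply(truth, function(st) {
        sample(colnames(confusion), 1, prob = confusion[st, ])
      }, "", USE.NAMES = FALSE)
    })
  })
}

#' Simulate paired measurements from two devices with known true ICC
#'
#' Subject true values are Normal(0, `between_subject_sd^2`); each device
#' adds independent Normal(0, `device_noise_sd^2`) noise, so the true
#' consistency ICC is `b^2 / (b^2 + d^2)`.
#'
#' @param n_subjects number of subjects (`>= 3`).
#' @param between_subject_sd,device_noise_sd standard deviations (`>= 0`).
#' @param seed integer seed.
#'
#' @return Tibble with columns `subject`, `device_a`, `device_b`.
#' @export
simulate_paired_measurements <- function(n_subjects, between_subject_sd,
                                         device_noise_sd, seed = 1) {
  if (n_subjects < 3) abort("`n_subjects` must be >= 3")
  if (between_subject_sd < 0 || device_noise_sd < 0) {
    abort("standard deviations must be >= 0")
  }
  with_seed(seed, {
    truth <- rnorm(n_subjects, 0, between_subject_sd)
    tibble(subject = seq_len(n_subjects),
           device_a = truth + rnorm(n_subjects, 0, device_noise_sd),
           device_b = truth + rnorm(n_subjects, 0, device_noise_sd))
  })
}

#' Write a synthetic night to plain-text fixtures
#'
#' Writes the recording as EDF, the hypnogram as one stage label per line
#' (30 s per line) and the ground-truth events as a tab-separated table.
#'
#' @param night list from [generate_recording()].
#' @param hypnogram the hypnogram the night was generated from.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_night <- function(night, hypnogram, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edf(night$recording, file.path(dir, "recording.edf"))
  writeLines(hypnogram, file.path(dir, "hypnogram.txt"))
  write.table(night$events, file.path(dir, "events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a plain-text hypnogram (one stage label per 30-s line)
#'
#' @param path file path.
#' @return Character vector of stage labels.
#' @export
read_hypnogram <- function(path) {
  h <- trimws(readLines(path))
  h <- h[nzchar(h)]
  assert_stages(h)
  h
}
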