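#' Multichannel recording object
#'
#' A `recording` holds a multichannel biopotential time series in microvolts
#' together with its sampling rate and per-channel metadata. Channels are
#' columns of a numeric matrix; each carries a label (e.g. `"C4-M1"`) and a
#' signal class (`"EEG"`, `"EOG"` or `"EMG"`) that downstream filtering uses
#' to pick the right passband.
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of channel labels (one per column).
#' @param classes character vector of channel classes, each one of
#'   `"EEG"`, `"EOG"`, `"EMG"`.
#'
#' @return An object of class `recording`.
#' @export
#' @examples
#' rec <- new_recording(matrix(rnorm(1000), ncol = 2), fs = 100,
#'                      labels = c("C4-M1", "E1-M2"),
#'                      classes = c("EEG", "EOG"))
#' rec
new_recording <- function(data, fs, labels, classes) {
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("`data` must be a numeric matrix.")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  if (length(labels) != ncol(data)) {
    abort("`labels` must have one entry per channel.")
  }
  if (ncol(data) > 0) {
    classes <- match.arg(classes, c("EEG", "EOG", "EMG"), several.ok = TRUE)
    if (length(classes) == 1L) classes <- rep(classes, ncol(data))
    if (length(classes) != ncol(data)) {
      abort("`classes` must have one entry per channel.")
    }
  } else {
    classes <- character(0)
  }
  colnames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = as.character(labels),
         classes = as.character(classes)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s), %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  ", paste(sprintf("%s[%s]", x$labels, x$classes), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

n_samples <- function(rec) nrow(rec$data)

#' Extract one channel of a recording by label
#'
#' @param rec a [new_recording()] object.
#' @param label channel label.
#' @return Numeric vector of samples (microvolts).
#' @export
rec_channel <- function(rec, label) {
  i <- match(label, rec$labels)
  if (is.na(i)) abort(sprintf("channel `%s` not found", label))
  rec$data[, i]
}

#' Split a recording into 30-second epochs aligned to a hypnogram
#'
#' Epoch `i` (1-based) covers samples `[(i-1)*30*fs, i*30*fs)`; a partial
#' trailing epoch is discarded. When the recording and the hypnogram imply
#' different epoch counts the minimum is used.
#'
#' @param recording a [new_recording()] object.
#' @param hypnogram character vector of per-epoch stage labels
#'   (`W`, `N1`, `N2`, `N3`, `REM`).
#' @param epoch_len_s epoch length in seconds (30 by convention).
#'
#' @return An `epoched_signal`: a list with `epochs` (array of dimension
#'   n_epochs x n_channels x samples-per-epoch), `stage`, `fs`, `labels`,
#'   `classes` and `epoch_len_s`.
#' @export
segment_epochs <- function(recording, hypnogram, epoch_len_s = 30) {
  assert_stages(hypnogram)
  spe <- round(epoch_len_s * recording$fs)
  n_ep <- min(floor(n_samples(recording) / spe), length(hypnogram))
  if (n_ep < 1) abort("zero usable epochs")
  arr <- array(NA_real_,
               dim = c(n_ep, ncol(recording$data), spe),
               dimnames = list(NULL, recording$labels, NULL))
  for (i in seq_len(n_ep)) {
    arr[i, , ] <- t(recording$data[((i - 1) * spe + 1):(i * spe), ,
                                   drop = FALSE])
  }
  structure(
    list(epochs = arr, stage = hypnogram[seq_len(n_ep)], fs = recording$fs,
         labels = recording$labels, classes = recording$classes,
         epoch_len_s = epoch_len_s),
    class = "epoched_signal"
  )
}

#' @export
print.epoched_signal <- function(x, ...) {
  cat(sprintf("<epoched_signal> %d epochs x %d channel(s) x %d samples @ %g Hz\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3], x$fs))
  print(table(factor(x$stage, levels = SLEEP_STAGES)))
  invisible(x)
}

#' Form referential derivations from raw electrode channels
#'
#' Each output channel is the samplewise difference `plus - minus`, e.g.
#' `F4-M1 = F4 - M1`. An empty derivation list returns an empty recording
#' with the same sampling rate.
#'
#' @param recording a [new_recording()] whose labels include the electrodes.
#' @param derivations data frame with columns `label`, `plus`, `minus` and
#'   optionally `class` (defaults to the class of the `plus` electrode).
#'
#' @return A `recording` of the derived channels.
#' @export
derive_channels <- function(recording, derivations) {
  derivations <- as_tibble(derivations)
  if (nrow(derivations) == 0) {
    return(new_recording(matrix(numeric(0), nrow = n_samples(recording),
                                ncol = 0),
                         fs = recording$fs, labels = character(0),
                         classes = character(0)))
  }
  for (el in unique(c(derivations$plus, derivations$minus))) {
    if (!el %in% recording$labels) {
      abort(sprintf("electrode `%s` missing from recording", el))
    }
  }
  out <- sapply(seq_len(nrow(derivations)), function(i) {
    rec_channel(recording, derivations$plus[i]) -
      rec_channel(recording, derivations$minus[i])
  })
  out <- matrix(out, nrow = n_samples(recording))
  classes <- if ("class" %in% names(derivations)) {
    derivations$class
  } else {
    recording$classes[match(derivations$plus, recording$labels)]
  }
  new_recording(out, recording$fs, derivations$label, classes)
}

#' Zero-phase bandpass filtering by channel class
#'
#' EEG and EOG channels are filtered 0.3-35 Hz and EMG channels 10-100 Hz
#' (both configurable). The filter is a 4th-order Butterworth applied
#' forward-backward (zero phase, effective 8th order), realized as a
#' high-pass/low-pass cascade for numerical stability at the very low
#' normalized corner frequency.
#'
#' @param recording a [new_recording()] object.
#' @param eeg_band,emg_band numeric length-2 passbands in Hz; the EEG band
#'   is also used for EOG channels.
#' @param order Butterworth order per pass (default 4).
#'
#' @return The filtered `recording`.
#' @export
bandpass_filter <- function(recording, eeg_band = c(0.3, 35),
                            emg_band = c(10, 100), order = 4) {
  fs <- recording$fs
  bands <- list(EEG = eeg_band, EOG = eeg_band, EMG = emg_band)
  for (cls in unique(recording$classes)) {
    if (fs <= 2 * bands[[cls]][2]) {
      abort(sprintf("fs = %g too low for %s band upper cutoff %g Hz",
                    fs, cls, bands[[cls]][2]))
    }
  }
  out <- recording
  for (j in seq_along(recording$labels)) {
    band <- bands[[recording$classes[j]]]
    out$data[, j] <- butter_bandpass_zerophase(recording$data[, j], fs,
                                               band[1], band[2], order)
  }
  out
}

# HP + LP Butterworth cascade, each applied with filtfilt (zero phase).
butter_bandpass_zerophase <- function(x, fs, low, high, order = 4) {
  hp <- signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, y)
}
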