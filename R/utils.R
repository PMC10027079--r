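# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All synthetic-data entry points use
# this so that a single integer seed fully determines their output without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a string tag, so that one
# user-facing seed splits deterministically into independent streams
# (per channel, per epoch, per subject, ...). Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 9973 + 1) %% 2147483646) + 1L
}

# Periodic Hann window of length n.
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
}

# Centered moving average; edges use the raw values (the window only
# matters in the interior where events live).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  sm <- stats::filter(x, rep(1 / width, width), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# Linear FFT convolution of x with kernel h, returning the "same"-size
# output aligned so sample i of the result corresponds to sample i of x
# given the kernel's center index (1-based).
fft_convolve_same <- function(x, h, center) {
  n <- length(x)
  l <- length(h)
  nfft <- stats::nextn(n + l - 1L, 2L)
  X <- fft(c(x, rep(0, nfft - n)))
  H <- fft(c(h, rep(0, nfft - l)))
  y <- fft(X * H, inverse = TRUE) / nfft
  y[(center):(center + n - 1L)]
}

assert_stages <- function(stages, arg = "hypnogram") {
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad) > 0) {
    abort(sprintf("unknown stage label(s) in `%s`: %s", arg,
                  paste(bad, collapse = ", ")))
  }
  invisible(stages)
}

# Logical mask over samples marking which belong to epochs of the given
# stages (30-s epochs, fs samples/s). Samples beyond the hypnogram are FALSE.
stage_sample_mask <- function(n_samples, fs, hypnogram, stages,
                              epoch_len_s = 30) {
  spe <- round(epoch_len_s * fs)
  mask <- rep(FALSE, n_samples)
  n_ep <- min(length(hypnogram), floor(n_samples / spe))
  if (n_ep < 1) return(mask)
  keep <- which(hypnogram[seq_len(n_ep)] %in% stages)
  for (k in keep) {
    mask[((k - 1) * spe + 1):(k * spe)] <- TRUE
  }
  mask
}
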