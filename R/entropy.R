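# Sample entropy and multiscale entropy (coarse-graining + SampEn).

#' Sample entropy of a series
#'
#' SampEn(m, r) = -ln(A / B), where B counts pairs of m-length templates
#' within tolerance (Chebyshev distance, self-matches excluded) and A the
#' same for length m + 1. The tolerance is `r_frac` times the sample SD of
#' the series unless an absolute tolerance `r` is given. Returns `NA` (with
#' a `reason` attribute) for constant series or when no matches exist.
#'
#' @param x numeric series of length `>= m + 2`.
#' @param m pattern length (2 by convention).
#' @param r_frac similarity criterion as a fraction of SD (0.15).
#' @param r absolute tolerance; overrides `r_frac` when given.
#'
#' @return Sample entropy in nats, or `NA`.
#' @export
#' @examples
#' sample_entropy(sin(seq(0, 20, by = 0.1)))
sample_entropy <- function(x, m = 2, r_frac = 0.15, r = NULL) {
  x <- as.numeric(x)
  if (length(x) < m + 2) abort("series must have at least m + 2 samples")
  if (is.null(r)) {
    s <- sd(x)
    if (is.na(s) || s == 0) {
      return(structure(NA_real_, reason = "constant series (SD = 0)"))
    }
    r <- r_frac * s
  }
  if (r <= 0) abort("tolerance must be positive")
  ab <- sampen_counts(x, as.integer(m), r)
  if (ab[1] == 0 || ab[2] == 0) {
    return(structure(NA_real_, reason = "no template matches"))
  }
  -log(ab[1] / ab[2])
}

#' Coarse-grain a series
#'
#' Non-overlapping means of `tau` consecutive samples; the result has
#' `floor(length(x) / tau)` points.
#'
#' @param x numeric series.
#' @param tau scale factor (positive integer).
#' @return The coarse-grained series.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1) abort("`tau` must be >= 1")
  if (tau == 1L) return(as.numeric(x))
  n <- floor(length(x) / tau)
  colMeans(matrix(x[seq_len(n * tau)], nrow = tau))
}

#' Multiscale entropy
#'
#' Sample entropy of coarse-grained versions of the series at the given
#' scales. The tolerance `r_frac * SD` is computed once from the original
#' series and reused at every scale (the convention that preserves the
#' characteristic white-noise/1-f crossover across scales).
#'
#' @param x numeric series; must be at least `max(scales) * (m + 2)` long.
#' @param scales integer scale factors (default 1, 3, 5, 7, 9).
#' @param m,r_frac sample-entropy parameters.
#'
#' @return An `mse_result` tibble with columns `scale`, `entropy`, `n`,
#'   and attributes `m`, `r_frac`, `tolerance`.
#' @export
multiscale_entropy <- function(x, scales = c(1, 3, 5, 7, 9), m = 2,
                               r_frac = 0.15) {
  x <- as.numeric(x)
  if (any(diff(scales) <= 0)) abort("`scales` must be strictly increasing")
  if (length(x) < max(scales) * (m + 2)) {
    abort("series too short for the largest scale")
  }
  s <- sd(x)
  if (is.na(s) || s == 0) abort("constant series (SD = 0)")
  tol <- r_frac * s
  res <- purrr::map_dfr(scales, function(tau) {
    cg <- coarse_grain(x, tau)
    tibble(scale = tau,
           entropy = as.numeric(sample_entropy(cg, m = m, r = tol)),
           n = length(cg))
  })
  attr(res, "m") <- m
  attr(res, "r_frac") <- r_frac
  attr(res, "tolerance") <- tol
  class(res) <- c("mse_result", class(res))
  res
}

#' Multiscale entropy per channel and stage
#'
#' Concatenates the filtered within-stage signal of each channel and runs
#' [multiscale_entropy()] on it. Long nights are capped at `max_samples`
#' leading samples per channel/stage to keep the quadratic-time template
#' count tractable; the cap is recorded in the output.
#'
#' @param epochs an `epoched_signal`.
#' @param stages,channels subsets (defaults: all stages, non-EMG channels).
#' @param scales,m,r_frac see [multiscale_entropy()].
#' @param max_samples per-series length cap (default 15000).
#'
#' @return Tibble with `channel`, `stage`, `scale`, `entropy`, `n`,
#'   `capped`.
#' @export
stage_entropy <- function(epochs, stages = NULL, channels = NULL,
                          scales = c(1, 3, 5, 7, 9), m = 2, r_frac = 0.15,
                          max_samples = 15000) {
  stages <- stages %||% unique(epochs$stage)
  channels <- channels %||% epochs$labels[epochs$classes != "EMG"]
  out <- list()
  for (ch in channels) {
    jc <- match(ch, epochs$labels)
    for (st in stages) {
      idx <- which(epochs$stage == st)
      if (length(idx) == 0) next
      x <- as.numeric(aperm(epochs$epochs[idx, jc, , drop = FALSE],
                            c(3, 1, 2)))
      capped <- length(x) > max_samples
      if (capped) x <- x[seq_len(max_samples)]
      mse <- multiscale_entropy(x, scales = scales, m = m, r_frac = r_frac)
      out[[length(out) + 1]] <- mutate(mse, channel = ch, stage = st,
                                       capped = capped)
    }
  }
  bind_rows(out) |>
    select("channel", "stage", "scale", "entropy", "n", "capped")
}

#' Plot multiscale entropy against scale
#'
#' @param object an `mse_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mse_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale, y = .data$entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Scale factor", y = "Sample entropy (nats)") +
    ggplot2::theme_minimal()
}
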