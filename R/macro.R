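# Macro sleep-architecture metrics from a hypnogram.

#' Macro sleep-architecture metrics
#'
#' Computes the standard whole-night summary from a 30-s hypnogram.
#' Definitions (all config-exposed; epochs are `epoch_min` minutes each):
#' sleep onset = first non-W epoch; TIB = full recording span; TST = total
#' sleep-epoch time; WASO = wake time between sleep onset and the final
#' sleep epoch; SLP_EFF = 100 * TST / TIB; SLP_MA_EFF = 100 * TST / (span
#' from onset through the final sleep epoch); REM_LAT = onset to first REM
#' epoch; PER_LAT = recording start to the first run of at least
#' `per_lat_run` consecutive sleep epochs; a NREM cycle is a NREM period of
#' at least `cycle_min_nrem` epochs terminated by a REM period of at least
#' `cycle_min_rem` epochs (the REM minimum is waived for the first cycle),
#' with NREMC reported as the mean cycle duration and the cycle count.
#'
#' @param hypnogram character vector of stage labels.
#' @param epoch_min epoch length in minutes (0.5 for 30-s epochs).
#' @param per_lat_run run length (epochs) defining persistent sleep.
#' @param cycle_min_nrem,cycle_min_rem cycle rule thresholds in epochs.
#'
#' @return One-row tibble with `TIB_min`, `TST_min`, `WASO_min`,
#'   `SLP_EFF`, `SLP_MA_EFF`, `REM_LAT_min`, `PER_LAT_min`, per-stage
#'   minutes and percent of TST (`N1_min`, `N1_pct`, ...), `NREMC_min`
#'   and `NREMC_count`. Latencies are `NA` when undefined (e.g. all-wake
#'   nights).
#' @export
#' @examples
#' macro_architecture(c("W", "W", "N2", "N2", "N3", "N3", "REM", "REM",
#'                      "W", "W"))
macro_architecture <- function(hypnogram, epoch_min = 0.5,
                               per_lat_run = 10, cycle_min_nrem = 30,
                               cycle_min_rem = 10) {
  assert_stages(hypnogram)
  n <- length(hypnogram)
  if (n < 1) abort("empty hypnogram")
  sleep <- hypnogram != "W"
  tib <- n * epoch_min
  tst <- sum(sleep) * epoch_min

  stage_min <- vapply(c("N1", "N2", "N3", "REM"),
                      function(s) sum(hypnogram == s) * epoch_min, 0)
  stage_pct <- if (tst > 0) 100 * stage_min / tst else rep(NA_real_, 4)

  if (tst == 0) {
    return(tibble(
      TIB_min = tib, TST_min = 0, WASO_min = 0, SLP_EFF = 0,
      SLP_MA_EFF = NA_real_, REM_LAT_min = NA_real_,
      PER_LAT_min = NA_real_,
      N1_min = 0, N1_pct = NA_real_, N2_min = 0, N2_pct = NA_real_,
      N3_min = 0, N3_pct = NA_real_, REM_min = 0, REM_pct = NA_real_,
      NREMC_min = NA_real_, NREMC_count = 0L))
  }

  onset <- which(sleep)[1]
  last_sleep <- tail(which(sleep), 1)
  period <- hypnogram[onset:last_sleep]
  waso <- sum(period == "W") * epoch_min
  span <- length(period) * epoch_min
  slp_eff <- 100 * tst / tib
  slp_ma_eff <- 100 * tst / span

  first_rem <- which(hypnogram == "REM")[1]
  rem_lat <- if (is.na(first_rem)) NA_real_ else
    (first_rem - onset) * epoch_min

  # persistent sleep latency: first run of >= per_lat_run sleep epochs
  r <- rle(sleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  per_idx <- which(r$values & r$lengths >= per_lat_run)
  per_lat <- if (length(per_idx) == 0) NA_real_ else
    (starts[per_idx[1]] - 1) * epoch_min

  cyc <- nrem_cycles(period, cycle_min_nrem, cycle_min_rem)
  nremc_min <- if (length(cyc) == 0) NA_real_ else mean(cyc) * epoch_min

  tibble(
    TIB_min = tib, TST_min = tst, WASO_min = waso, SLP_EFF = slp_eff,
    SLP_MA_EFF = slp_ma_eff, REM_LAT_min = rem_lat,
    PER_LAT_min = per_lat,
    N1_min = stage_min[["N1"]], N1_pct = stage_pct[["N1"]],
    N2_min = stage_min[["N2"]], N2_pct = stage_pct[["N2"]],
    N3_min = stage_min[["N3"]], N3_pct = stage_pct[["N3"]],
    REM_min = stage_min[["REM"]], REM_pct = stage_pct[["REM"]],
    NREMC_min = nremc_min, NREMC_count = length(cyc))
}

# NREM/REM cycle segmentation within the sleep period (onset..last sleep
# epoch). REM runs are scanned in order; a run closes a block if it has
# >= min_rem epochs or no block has been closed yet (first-cycle
# exemption). A closing run always ends the current block; the block is
# recorded as a cycle (length = block start through REM run end) iff its
# pre-REM part contains >= min_nrem NREM epochs. Returns cycle lengths in
# epochs.
nrem_cycles <- function(period, min_nrem = 30, min_rem = 10) {
  is_rem <- period == "REM"
  r <- rle(is_rem)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cycles <- numeric(0)
  block_start <- 1
  closed_any <- FALSE
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    if (starts[k] <= block_start) {  # REM at block start: absorb, no cycle
      block_start <- ends[k] + 1
      next
    }
    closes <- r$lengths[k] >= min_rem || !closed_any
    if (!closes) next
    nrem_part <- period[block_start:(starts[k] - 1)]
    if (sum(nrem_part %in% c("N1", "N2", "N3")) >= min_nrem) {
      cycles <- c(cycles, ends[k] - block_start + 1)
    }
    closed_any <- TRUE
    block_start <- ends[k] + 1
  }
  cycles
}

#' Plot a hypnogram
#'
#' Standard staircase plot with depth increasing downward.
#'
#' @param hypnogram character vector of stage labels.
#' @param epoch_min epoch length in minutes.
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(hypnogram, epoch_min = 0.5) {
  depth <- c(W = 0, REM = 1, N1 = 2, N2 = 3, N3 = 4)
  df <- tibble(time_min = (seq_along(hypnogram) - 1) * epoch_min,
               depth = depth[hypnogram])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_reverse(breaks = unname(depth),
                             labels = names(depth)) +
    ggplot2::labs(x = "Time (min)", y = NULL) +
    ggplot2::theme_minimal()
}
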