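# End-to-end pipeline: synthesize (or load) nights for two devices,
# preprocess, extract multilevel features, detect events, compute macro
# architecture and agreement tables, and write tidy outputs plus a
# manifest.

#' Build a pipeline configuration
#'
#' All module defaults are collected here and can be overridden. The one
#' `seed` drives every random stream in the run.
#'
#' @param n_subjects number of synthetic subjects (nights).
#' @param n_epochs 30-s epochs per night.
#' @param proportions stage proportions for [generate_hypnogram()].
#' @param montage channel montage ([default_montage()]).
#' @param profiles stage profiles ([default_stage_profiles()]).
#' @param fs sampling rate in Hz.
#' @param device_noise_uv RMS of the white measurement noise added to the
#'   second device's copy of each night.
#' @param event_channel channel used for spindle/SO detection (default:
#'   first EEG channel).
#' @param spindle,so detector parameter objects.
#' @param scorer_accuracy diagonal of the scorer confusion model.
#' @param n_scorers number of simulated scorers.
#' @param mse_max_samples per-series cap for [stage_entropy()].
#' @param seed integer master seed.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 3, n_epochs = 20,
                       proportions = c(W = 0.03, N1 = 0.02, N2 = 0.50,
                                       N3 = 0.20, REM = 0.25),
                       montage = default_montage(),
                       profiles = default_stage_profiles(),
                       fs = 500, device_noise_uv = 2,
                       event_channel = NULL,
                       spindle = spindle_params(),
                       so = so_params(),
                       scorer_accuracy = 0.85, n_scorers = 3,
                       mse_max_samples = 15000, seed = 1) {
  assert_stages(names(proportions), "proportions")
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("`proportions` must sum to 1")
  }
  cfg <- list(n_subjects = n_subjects, n_epochs = n_epochs,
              proportions = proportions, montage = as_tibble(montage),
              profiles = profiles, fs = fs,
              device_noise_uv = device_noise_uv,
              event_channel = event_channel, spindle = spindle, so = so,
              scorer_accuracy = scorer_accuracy, n_scorers = n_scorers,
              mse_max_samples = mse_max_samples, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

# Per-channel/per-stage feature extraction for one preprocessed night.
night_features <- function(epochs, cfg) {
  stages_present <- intersect(SLEEP_STAGES, unique(epochs$stage))
  spectral_stages <- intersect(c("N2", "N3", "REM"), stages_present)
  rows <- list()
  if (length(spectral_stages) > 0) {
    psd <- welch_psd(epochs, stages = spectral_stages)
    relp <- relative_band_power(psd)
    rows$relp <- relp |>
      mutate(metric = paste0("relpsd_", .data$band), value = .data$rel_power) |>
      select("channel", "stage", "metric", "value")
    rows$slope <- spectral_slope(psd) |>
      mutate(metric = "psd_slope", value = .data$slope) |>
      select("channel", "stage", "metric", "value")
    erp <- epoch_band_powers(epochs, stages = spectral_stages)
    rows$si <- slowing_index(erp) |>
      mutate(metric = "slowing_index", value = .data$si) |>
      select("channel", "stage", "metric", "value")
    mse <- stage_entropy(epochs, stages = spectral_stages,
                         max_samples = cfg$mse_max_samples)
    rows$mse <- mse |>
      mutate(metric = paste0("mse_scale", .data$scale),
             value = .data$entropy) |>
      select("channel", "stage", "metric", "value")
  }
  # percentile features on the whole-night signal per channel
  ch_eeg <- epochs$labels[epochs$classes != "EMG"]
  rows$pctl <- purrr::map_dfr(ch_eeg, function(ch) {
    jc <- match(ch, epochs$labels)
    x <- as.numeric(aperm(epochs$epochs[, jc, , drop = FALSE], c(3, 1, 2)))
    pf <- percentile_features(x)
    tibble(channel = ch, stage = "ALL",
           metric = paste0("pctl_", pf$percentile), value = pf$value)
  })
  bind_rows(rows)
}

#' Run the full multilevel analysis pipeline
#'
#' For each synthetic subject the pipeline generates a hypnogram and an
#' 8-channel night with ground-truth events, simulates a second device by
#' adding independent measurement noise, and runs both copies through
#' preprocessing (class-specific bandpass, 30-s epoching), spectral
#' (relative band power, power-law slope, slowing index), entropy,
#' percentile and event-level feature extraction plus macro architecture.
#' Scorer hypnograms are simulated from the truth and pairwise kappas
#' computed; per-metric between-device ICCs are computed across subjects.
#' Identical config and seed give byte-identical output tables.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; created if needed. `NULL` skips
#'   writing.
#'
#' @return Invisibly, a list with `features`, `events`, `macro`,
#'   `agreement`, `kappa` tibbles and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  cfg <- config
  if (!inherits(cfg, "run_config")) abort("`config` must be a run_config")
  features <- list(); events_tbl <- list(); macro_tbl <- list()
  kappa_tbl <- list()

  for (s in seq_len(cfg$n_subjects)) {
    sseed <- derive_seed(cfg$seed, paste0("subject:", s))
    hyp <- generate_hypnogram(cfg$n_epochs, cfg$proportions, seed = sseed)
    night <- generate_recording(hyp, cfg$profiles, cfg$montage,
                                fs = cfg$fs,
                                seed = derive_seed(sseed, "night"))
    noise <- with_seed(derive_seed(sseed, "device_b"), {
      matrix(rnorm(length(night$recording$data), 0, cfg$device_noise_uv),
             nrow = nrow(night$recording$data))
    })
    rec_b <- night$recording
    rec_b$data <- rec_b$data + noise
    devices <- list(A = night$recording, B = rec_b)

    ev_ch <- cfg$event_channel %||%
      cfg$montage$label[cfg$montage$class == "EEG"][1]

    for (dv in names(devices)) {
      filt <- bandpass_filter(devices[[dv]])
      epochs <- segment_epochs(filt, hyp)
      ft <- night_features(epochs, cfg) |>
        mutate(subject = s, device = dv)
      features[[length(features) + 1]] <- ft

      x <- rec_channel(filt, ev_ch)
      sp_slow <- detect_spindles(x, cfg$fs, hyp,
                                 modify_params(cfg$spindle, fc = 11))
      sp_fast <- detect_spindles(x, cfg$fs, hyp,
                                 modify_params(cfg$spindle, fc = 15))
      sos <- detect_slow_oscillations(x, cfg$fs, hyp, cfg$so)
      ev <- bind_rows(sp_slow, sp_fast, sos)
      if (nrow(ev) > 0) {
        events_tbl[[length(events_tbl) + 1]] <-
          mutate(ev, subject = s, device = dv, channel = ev_ch)
      }
      macro_tbl[[length(macro_tbl) + 1]] <-
        macro_architecture(hyp) |> mutate(subject = s, device = dv)
    }

    scorers <- simulate_scorers(hyp, scorer_confusion(cfg$scorer_accuracy),
                                cfg$n_scorers,
                                seed = derive_seed(sseed, "scorers"))
    for (i in seq_len(cfg$n_scorers - 1)) {
      for (j in (i + 1):cfg$n_scorers) {
        kp <- cohen_kappa(scorers[[i]], scorers[[j]])
        kappa_tbl[[length(kappa_tbl) + 1]] <-
          tidy(kp) |> mutate(subject = s, scorer_a = i, scorer_b = j)
      }
    }
  }

  features <- bind_rows(features)
  events_tbl <- if (length(events_tbl) > 0) bind_rows(events_tbl) else
    tibble()
  macro_tbl <- bind_rows(macro_tbl)
  kappa_tbl <- bind_rows(kappa_tbl)

  # between-device ICC per metric/channel/stage across subjects
  agreement <- features |>
    tidyr::pivot_wider(names_from = "device", values_from = "value") |>
    group_by(.data$metric, .data$channel, .data$stage) |>
    dplyr::reframe({
      ok <- is.finite(.data$A) & is.finite(.data$B)
      if (sum(ok) >= 3 && sd(.data$A[ok]) > 0) {
        tidy(icc_consistency(cbind(.data$A[ok], .data$B[ok])))
      } else {
        tibble(method = "icc_consistency", estimate = NA_real_,
               conf.low = NA_real_, conf.high = NA_real_,
               p.value = NA_real_, n = sum(ok),
               interpretation = NA_character_)
      }
    })

  manifest <- list(
    package = "somnarch",
    version = as.character(utils::packageVersion("somnarch")),
    seed = cfg$seed,
    n_subjects = cfg$n_subjects,
    n_epochs = cfg$n_epochs,
    config_hash = rlang::hash(cfg),
    tables = c("features.tsv", "events.tsv", "macro.tsv",
               "agreement.tsv", "kappa.tsv"))

  out <- list(features = features, events = events_tbl, macro = macro_tbl,
              agreement = agreement, kappa = kappa_tbl,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) {
      write.table(as.data.frame(df), file.path(out_dir, f), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    wr(features, "features.tsv")
    wr(events_tbl, "events.tsv")
    wr(macro_tbl, "macro.tsv")
    wr(agreement, "agreement.tsv")
    wr(kappa_tbl, "kappa.tsv")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "manifest.json"))
  }
  invisible(out)
}

# Override fields of a parameter object, revalidating via its constructor.
modify_params <- function(params, ...) {
  ctor <- if (inherits(params, "spindle_params")) spindle_params else
    so_params
  args <- modifyList(unclass(params), list(...))
  do.call(ctor, args)
}
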