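# End-to-end synthetic study driver.
#
# Bundles the full pipeline on generated data: scenes with planted events,
# simulated listeners, CNN activations and surprisal, signal conditioning,
# and the recovery analyses (event detection rate, planted layer-profile
# trend, event-prediction benchmark).  This is the standard benchmark used
# by the package's tests and by scripts/acceptance.R.

#' Place an irregularly defined series on the scene's uniform 10 Hz grid
#'
#' Linearly interpolates `(times, values)` onto the grid `0, 1/rate, ...`
#' spanning `duration_s`, extending the first/last defined value over the
#' head and tail (e.g. the undefined early frames of a surprisal track).
#'
#' @param times,values Sample times (s) and values; `NA` values are
#'   dropped before interpolation.
#' @param duration_s Grid span in seconds.
#' @param rate Grid rate in Hz (default 10).
#' @return Numeric vector of length `floor(duration_s * rate)` with
#'   attribute `"rate"`.
#' @export
series_on_grid <- function(times, values, duration_s, rate = 10) {
  ok <- is.finite(values)
  grid <- (seq_len(floor(duration_s * rate)) - 1L) / rate
  y <- approx(times[ok], values[ok], xout = grid, rule = 2L)$y
  attr(y, "rate") <- rate
  y
}

#' Run the synthetic benchmark study
#'
#' Generates `n_scenes` scenes (alternating sparse and dense), simulates
#' `n_subjects` listeners per scene, detects salient events from the
#' salience curves, and (unless `cnn = FALSE`) computes the six layers'
#' surprisal tracks from a seeded-random network and conditions them for
#' correlation analysis.
#'
#' @param n_scenes Number of scenes (default 6).
#' @param duration_s Scene length in seconds (default 30).
#' @param n_subjects Simulated listeners per scene (default 20).
#' @param event_gain Event-locking gain of the listener model (default 30).
#' @param seed Integer master seed.
#' @param cnn Run the CNN/surprisal stage (default TRUE).
#' @param network Optional prebuilt `audio_cnn` to reuse.
#' @param hop_s Activation hop in seconds (default 0.1).
#' @return A list of class `synthetic_study` with one entry per scene:
#'   `scene`, `salience`, `events` (detected), `conditioned_salience`, and
#'   (with `cnn`) `surprisal` (tibble) plus `conditioned_surprisal` (named
#'   list of conditioned per-layer series).
#' @export
run_synthetic_study <- function(n_scenes = 6, duration_s = 30, n_subjects = 20,
                                event_gain = 30, seed = 1L, cnn = TRUE,
                                network = NULL, hop_s = 0.1) {
  if (cnn && is.null(network)) network <- build_network(cnn_config(seed = seed))
  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    density <- if (i %% 2L == 1L) "sparse" else "dense"
    cfg <- scene_config(duration_s = duration_s, density = density,
                        seed = seed + i)
    scene <- gen_scene(cfg)
    subj <- subject_model(n_subjects = n_subjects, event_gain = event_gain,
                          seed = seed + 100L + i)
    sal <- gen_salience(scene, subj)
    events <- detect_salient_events(sal, annotations = scene$annotations)
    entry <- list(
      scene = scene, salience = sal, events = events,
      conditioned_salience = condition_series(sal$percent, rate = 10,
                                              origin = "salience")
    )
    if (cnn) {
      acts <- activation_timeseries(network, scene, hop_s = hop_s)
      surp <- compute_surprisal(acts)
      entry$surprisal <- surp
      entry$conditioned_surprisal <- lapply(ANALYZED_LAYERS, function(l) {
        s <- surp[surp$layer == l, ]
        g <- series_on_grid(s$time, s$surprisal, scene$duration_s)
        condition_series(g, rate = 10, origin = "surprisal")
      })
      names(entry$conditioned_surprisal) <- ANALYZED_LAYERS
    }
    scenes[[i]] <- entry
  }
  structure(list(scenes = scenes, seed = seed, duration_s = duration_s),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d scenes x %.0f s (seed %d)\n",
              length(x$scenes), x$duration_s, x$seed))
  invisible(x)
}

#' Planted-event recovery rate of the behavioral pipeline
#'
#' Fraction of planted (ground-truth) event onsets for which a detected
#' salient event lies within `tol_s` seconds of the onset plus the
#' listeners' motor delay.  Matching is against the full candidate set of
#' the detector (every derivative peak above the noise floor): the
#' strongest-50% cut applied by [detect_salient_events()] is an event
#' *selection* step for the downstream event-based analyses, deliberately
#' discarding weaker events, and so is not part of detection sensitivity.
#'
#' @param study A `synthetic_study`.
#' @param tol_s Matching tolerance in seconds (default 1).
#' @param motor_delay_s Motor delay added to planted onsets before
#'   matching (default 1.4, the listener-model default).
#' @return A one-row tibble: `n_planted`, `n_recovered`, `rate`.
#' @export
study_event_recovery <- function(study, tol_s = 1, motor_delay_s = 1.4) {
  n_planted <- 0L
  n_recovered <- 0L
  for (entry in study$scenes) {
    planted <- entry$scene$annotations$onset_s + motor_delay_s
    detected <- attr(entry$events, "candidates")$time_s
    n_planted <- n_planted + length(planted)
    if (length(detected) == 0L) next
    for (t_ev in planted) {
      if (min(abs(detected - t_ev)) <= tol_s) n_recovered <- n_recovered + 1L
    }
  }
  tibble::tibble(n_planted = n_planted, n_recovered = n_recovered,
                 rate = n_recovered / n_planted)
}

#' Recover a planted early-vs-deep correlation profile
#'
#' Plants a known correlation structure across layers: for each scene and
#' layer, a band-energy surrogate is generated from that layer's
#' conditioned surprisal with a mixing weight that declines with depth
#' (via [gen_band_energy()]), and the maximum lagged correlation between
#' surprisal and surrogate is measured.  The resulting layer profile is
#' fed to [layer_trend()]; with declining weights the recovered slope
#' should be negative.
#'
#' @param study A `synthetic_study` run with `cnn = TRUE`.
#' @param weights Planted mixing weight per layer, shallow to deep
#'   (default declining from 1 to 0.2).
#' @param noise_sd Surrogate noise SD (default 0.6).
#' @param lag_s Planted lag in seconds (default 0.5).
#' @param seed Integer seed for the surrogate noise.
#' @return A list: `profile` (tibble `layer`, `value` with one replicate
#'   per scene), `trend` (a `layer_trend`).
#' @export
study_trend_recovery <- function(study, weights = seq(1, 0.2, length.out = 6),
                                 noise_sd = 0.6, lag_s = 0.5, seed = 1L) {
  rows <- list()
  for (i in seq_along(study$scenes)) {
    entry <- study$scenes[[i]]
    if (is.null(entry$conditioned_surprisal)) {
      stop("study was run without the CNN stage", call. = FALSE)
    }
    for (l in seq_along(ANALYZED_LAYERS)) {
      layer <- ANALYZED_LAYERS[l]
      drv <- zscore(entry$conditioned_surprisal[[layer]])
      mix <- eeg_mix_config(n_channels = 1L,
                            band_weights = c(drive = weights[l]),
                            planted_lag_s = lag_s, noise_sd = noise_sd,
                            seed = seed + 1000L * i + l)
      surrogate <- gen_band_energy(drv, mix)
      res <- max_lagged_correlation(drv, surrogate$energy, rate = 10)
      rows[[length(rows) + 1L]] <- tibble::tibble(layer = layer, value = res$r)
    }
  }
  profile <- dplyr::bind_rows(rows)
  list(profile = profile, trend = layer_trend(profile))
}

#' Bin table for the event-prediction benchmark
#'
#' Builds the overlapping-bin predictor table for a study scene set:
#' slopes of the acoustic feature tracks, plus a `surprisal` predictor
#' that carries event information statistically independent of the
#' acoustic tracks (an event-locked bump train with additive noise,
#' generated under `seed`).  Bins from all scenes are concatenated;
#' labels mark bins containing a detected salient event.
#'
#' @param study A `synthetic_study` (the CNN stage is not required).
#' @param feature_names Acoustic tracks whose slopes enter the table
#'   (default loudness, brightness, flatness, roughness).
#' @param info_sd Noise SD of the planted surprisal predictor
#'   (default 1; larger means less informative).
#' @param seed Integer seed.
#' @return A bin table (tibble) suitable for [lda_classify()], with the
#'   planted predictor in column `surprisal`.
#' @export
study_bin_table <- function(study,
                            feature_names = c("loudness", "brightness",
                                              "flatness", "roughness"),
                            info_sd = 1, seed = 1L) {
  tabs <- vector("list", length(study$scenes))
  for (i in seq_along(study$scenes)) {
    entry <- study$scenes[[i]]
    feats <- compute_acoustic_features(entry$scene)
    n <- nrow(feats)
    cols <- tibble::tibble(time = feats$time)
    for (f in feature_names) {
      cols[[paste0("slope_", f)]] <- feature_slope(feats[[f]], rate = 10)
    }
    ev_times <- entry$events$time_s
    cols$surprisal <- with_seed(seed + i, {
      bump <- numeric(n)
      for (t_ev in ev_times) {
        bump <- bump + exp(-((feats$time - t_ev)^2) / (2 * 0.4^2))
      }
      zscore(bump) + rnorm(n, sd = info_sd)
    })
    tabs[[i]] <- build_bins(cols, entry$events, rate = 10)
  }
  out <- dplyr::bind_rows(tabs)
  attr(out, "rate") <- 10
  out
}
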