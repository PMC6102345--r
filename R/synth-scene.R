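#' Scene configuration for the synthetic soundscape generator
#'
#' Describes a synthetic natural-scene surrogate: a 1/f background with a
#' set of planted acoustic events of known onset, category, level and
#' duration.  Scenes come in two densities mirroring the sparse/dense
#' distinction used throughout the analyses: "sparse" scenes have few,
#' clearly isolated events, while "dense" scenes have at least three times
#' the event rate.
#'
#' When `event_specs` is `NULL`, events are drawn at random (under `seed`)
#' at the density's nominal rate: 3 events per minute for sparse scenes and
#' 9 per minute for dense scenes, with categories sampled uniformly from
#' the five analyzed classes, levels around -12 dB and durations between
#' 0.5 and 1.5 s.  Event onsets keep a minimum separation of one second.
#'
#' @param duration_s Scene length in seconds (> 0, default 120).
#' @param sample_rate Sampling rate in Hz (default 22050).
#' @param density `"sparse"` or `"dense"`.
#' @param event_specs Optional tibble/data frame with columns `onset_s`,
#'   `category` (one of `"speech"`, `"music"`, `"vocal"`, `"vehicle"`,
#'   `"tapping"`), `level_db` (dB re unit RMS) and `duration_s`.
#' @param background_level_db Background 1/f-noise level in dB re unit RMS;
#'   `-Inf` yields a silent background.
#' @param seed Integer seed; fixed seed gives byte-identical scenes.
#'
#' @return An object of class `scene_config`.
#' @seealso [gen_scene()]
#' @export
scene_config <- function(duration_s = 120, sample_rate = 22050,
                         density = c("sparse", "dense"), event_specs = NULL,
                         background_level_db = -30, seed = 1L) {
  density <- match.arg(density)
  stopifnot_scalar_number(duration_s, "duration_s", lower = 1e-6)
  stopifnot_scalar_number(sample_rate, "sample_rate", lower = 1)
  if (!identical(background_level_db, -Inf)) {
    stopifnot_scalar_number(background_level_db, "background_level_db")
  }
  if (is.null(event_specs)) {
    rate_per_s <- if (density == "sparse") 3 / 60 else 9 / 60
    event_specs <- with_seed(seed + 1000L, {
      n_ev <- max(0L, round(rate_per_s * duration_s))
      draw_event_specs(n_ev, duration_s)
    })
  } else {
    event_specs <- tibble::as_tibble(event_specs)
    needed <- c("onset_s", "category", "level_db", "duration_s")
    if (!all(needed %in% names(event_specs))) {
      stop("`event_specs` needs columns onset_s, category, level_db, duration_s",
           call. = FALSE)
    }
  }
  if (nrow(event_specs) > 0) {
    bad <- event_specs$onset_s < 0 | event_specs$onset_s >= duration_s |
      event_specs$onset_s + event_specs$duration_s > duration_s
    if (any(bad)) {
      stop("event(s) extend beyond the scene bounds: ",
           paste(round(event_specs$onset_s[bad], 2), collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(event_specs$category, EVENT_CATEGORIES)
    if (length(unknown)) {
      stop("unknown event category: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(duration_s = duration_s, sample_rate = sample_rate, density = density,
         event_specs = event_specs, background_level_db = background_level_db,
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' The five analyzed event categories
#' @format Character vector of length five.
#' @export
EVENT_CATEGORIES <- c("speech", "music", "vocal", "vehicle", "tapping")

draw_event_specs <- function(n_ev, duration_s) {
  if (n_ev == 0L) {
    return(tibble::tibble(onset_s = numeric(), category = character(),
                          level_db = numeric(), duration_s = numeric()))
  }
  # rejection-sample onsets with >= 1 s separation, leaving headroom for
  # the longest event token
  max_dur <- 1.5
  for (i in 1:50) {
    onsets <- sort(runif(n_ev, 0.5, duration_s - max_dur - 0.1))
    if (n_ev == 1L || min(diff(onsets)) >= 1) break
  }
  tibble::tibble(
    onset_s = onsets,
    category = sample(EVENT_CATEGORIES, n_ev, replace = TRUE),
    level_db = runif(n_ev, -15, -9),
    duration_s = runif(n_ev, 0.5, max_dur)
  )
}

#' Generate a synthetic audio scene
#'
#' Renders the scene described by a [scene_config()]: a 1/f background at
#' the configured level plus parametric event tokens, one per planted
#' event.  Tokens are synthesized per category so that categories are
#' acoustically distinct: speech-like events are harmonic complexes with a
#' pitch glide and syllabic (4 Hz) amplitude modulation; music events are
#' short note sequences; vocalizations are harmonic tones with vibrato;
#' vehicle events are low-frequency band-limited noise swells; tapping
#' events are trains of impulsive bursts.
#'
#' @param config A [scene_config()].
#' @return An `audio_scene`: list with `samples` (numeric waveform),
#'   `sample_rate`, `duration_s`, `density` and `annotations` (tibble of
#'   ground-truth events).
#' @examples
#' sc <- gen_scene(scene_config(duration_s = 10, density = "sparse", seed = 3))
#' sc
#' @export
gen_scene <- function(config) {
  if (!inherits(config, "scene_config")) stop("`config` must be a scene_config")
  n <- round(config$duration_s * config$sample_rate)
  with_seed(config$seed, {
    if (identical(config$background_level_db, -Inf)) {
      samples <- numeric(n)
    } else {
      samples <- pink_noise(n) * 10^(config$background_level_db / 20)
    }
    ev <- config$event_specs
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        tok <- synth_event_token(ev$category[i], ev$duration_s[i],
                                 config$sample_rate, ev$level_db[i])
        i0 <- round(ev$onset_s[i] * config$sample_rate) + 1L
        i1 <- i0 + length(tok) - 1L
        if (i1 > n) stop("event extends beyond waveform bounds", call. = FALSE)
        samples[i0:i1] <- samples[i0:i1] + tok
      }
    }
    audio_scene(samples, config$sample_rate, annotations = ev,
                density = config$density)
  })
}

#' Construct an audio scene object
#'
#' @param samples Numeric mono waveform (finite values).
#' @param sample_rate Sampling rate in Hz.
#' @param annotations Optional tibble of ground-truth events
#'   (`onset_s`, `category`, `level_db`, `duration_s`).
#' @param density Optional `"sparse"`/`"dense"` label.
#' @return An object of class `audio_scene`.
#' @export
audio_scene <- function(samples, sample_rate, annotations = NULL, density = NA_character_) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("`samples` must be a finite numeric vector", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         duration_s = length(samples) / sample_rate,
         annotations = if (is.null(annotations)) NULL else tibble::as_tibble(annotations),
         density = density),
    class = "audio_scene"
  )
}

#' @export
print.audio_scene <- function(x, ...) {
  cat(sprintf("<audio_scene> %.2f s @ %g Hz (%s), %d annotated event(s)\n",
              x$duration_s, x$sample_rate,
              ifelse(is.na(x$density), "unlabeled", x$density),
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

# --- event token synthesis ---------------------------------------------------

synth_event_token <- function(category, duration_s, sample_rate, level_db) {
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  x <- switch(
    category,
    speech = {
      f0 <- 120 + 60 * sin(2 * pi * t / duration_s)     # pitch glide
      phase <- 2 * pi * cumsum(f0) / sample_rate
      y <- numeric(n)
      for (h in 1:8) y <- y + sin(h * phase) / h
      y * (0.6 + 0.4 * sin(2 * pi * 4 * t))             # syllabic AM
    },
    music = {
      notes <- c(262, 330, 392, 523)                    # arpeggio
      nn <- max(1L, length(notes))
      seg <- ceiling(n / nn)
      y <- numeric(n)
      for (k in seq_len(nn)) {
        i0 <- (k - 1L) * seg + 1L
        i1 <- min(k * seg, n)
        tt <- (0:(i1 - i0)) / sample_rate
        env <- exp(-tt * 4)
        for (h in 1:4) {
          y[i0:i1] <- y[i0:i1] + env * sin(2 * pi * h * notes[k] * tt) / h
        }
      }
      y
    },
    vocal = {
      f0 <- 300 * (1 + 0.03 * sin(2 * pi * 6 * t))      # vibrato
      phase <- 2 * pi * cumsum(f0) / sample_rate
      sin(phase) + 0.5 * sin(2 * phase) + 0.25 * sin(3 * phase)
    },
    vehicle = {
      noise <- rnorm(n)
      X <- fft(noise)
      f <- (seq_len(n) - 1L) * sample_rate / n
      f <- pmin(f, sample_rate - f)
      X[f < 60 | f > 400] <- 0
      y <- Re(fft(X, inverse = TRUE) / n)
      y * sin(pi * t / duration_s)^2                    # swell
    },
    tapping = {
      y <- numeric(n)
      n_taps <- max(3L, round(duration_s * 6))
      tap_at <- round(seq(1, n - sample_rate * 0.02, length.out = n_taps))
      burst_n <- round(0.005 * sample_rate)
      for (i0 in tap_at) {
        idx <- i0:(i0 + burst_n - 1L)
        y[idx] <- y[idx] + rnorm(burst_n) * exp(-(0:(burst_n - 1L)) / (burst_n / 4))
      }
      y
    },
    stop("unknown event category: ", category, call. = FALSE)
  )
  # cosine on/off ramps (10 ms) to avoid clicks, then set RMS to level_db
  ramp_n <- min(round(0.01 * sample_rate), floor(n / 2))
  if (ramp_n > 0) {
    ramp <- sin(pi / 2 * (seq_len(ramp_n) / ramp_n))^2
    x[seq_len(ramp_n)] <- x[seq_len(ramp_n)] * ramp
    x[(n - ramp_n + 1L):n] <- x[(n - ramp_n + 1L):n] * rev(ramp)
  }
  rms <- sqrt(mean(x^2))
  if (rms > 0) x <- x / rms * 10^(level_db / 20)
  x
}
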