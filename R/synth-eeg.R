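#' Configuration for the EEG-like band-energy surrogate
#'
#' Describes how band-energy channels are mixed from a driver signal: each
#' channel/band track is `band_weight * lag-shifted driver + noise`, then
#' z-scored.  This generates band-level series directly at 10 Hz with a
#' known (planted) lag and weight, so the lagged-correlation machinery has
#' a ground truth to recover.
#'
#' @param n_channels Number of channels (>= 1, default 4).
#' @param band_weights Named numeric vector of per-band mixing weights;
#'   names default to the six analysis bands (see [band_definitions()]).
#' @param planted_lag_s Lag in seconds applied to the driver, in
#'   \[-3, 3\]; positive means the band energy follows the driver.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param groups Optional character vector of electrode-group labels, one
#'   per channel (e.g. `"frontal"`, `"central"`); recycled if length 1.
#' @param seed Integer seed.
#' @return An object of class `eeg_mix_config`.
#' @export
eeg_mix_config <- function(n_channels = 4,
                           band_weights = c(Delta = 1, Theta = 0.5, Alpha = 0.5,
                                            Beta = 1, Gamma = 1, HighGamma = 1),
                           planted_lag_s = 0, noise_sd = 0.5,
                           groups = NULL, seed = 1L) {
  if (n_channels < 1) stop("`n_channels` must be at least 1", call. = FALSE)
  stopifnot_scalar_number(planted_lag_s, "planted_lag_s", -3, 3)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(names(band_weights))) stop("`band_weights` must be named", call. = FALSE)
  if (is.null(groups)) {
    groups <- rep(c("frontal", "central"), length.out = n_channels)
  } else {
    groups <- rep(groups, length.out = n_channels)
  }
  structure(
    list(n_channels = as.integer(n_channels), band_weights = band_weights,
         planted_lag_s = planted_lag_s, noise_sd = noise_sd,
         groups = groups, seed = as.integer(seed)),
    class = "eeg_mix_config"
  )
}

#' Generate band-energy channels with a planted correlation to a driver
#'
#' @param driver Numeric driver series sampled at 10 Hz (e.g. a layer's
#'   surprisal track).
#' @param mix An [eeg_mix_config()].
#' @param rate Sampling rate of `driver` in Hz (default 10).
#' @return A long tibble with columns `channel`, `band`, `time`, `energy`
#'   (z-scored per channel x band), carrying the channel-to-group map in
#'   attribute `"groups"` and the planted ground truth in attribute
#'   `"truth"`.
#' @export
gen_band_energy <- function(driver, mix, rate = 10) {
  if (!inherits(mix, "eeg_mix_config")) stop("`mix` must be an eeg_mix_config")
  if (any(!is.finite(driver))) stop("`driver` must be finite", call. = FALSE)
  n <- length(driver)
  lag_n <- round(mix$planted_lag_s * rate)
  shifted <- shift_series(driver, lag_n)
  times <- (seq_len(n) - 1L) / rate
  bands <- names(mix$band_weights)
  with_seed(mix$seed, {
    rows <- vector("list", mix$n_channels * length(bands))
    k <- 0L
    for (ch in seq_len(mix$n_channels)) {
      for (b in seq_along(bands)) {
        w <- mix$band_weights[[b]]
        y <- w * shifted + rnorm(n, sd = mix$noise_sd)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          channel = sprintf("ch%02d", ch), band = bands[b],
          time = times, energy = zscore(y)
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "groups") <- setNames(mix$groups, sprintf("ch%02d", seq_len(mix$n_channels)))
    attr(out, "truth") <- list(lag_s = mix$planted_lag_s,
                               band_weights = mix$band_weights,
                               noise_sd = mix$noise_sd)
    attr(out, "rate") <- rate
    out
  })
}

# shift by `lag_n` samples (positive = delay), holding edge values
shift_series <- function(x, lag_n) {
  n <- length(x)
  if (lag_n == 0L) return(x)
  if (lag_n > 0L) c(rep(x[1L], lag_n), x[seq_len(n - lag_n)])
  else c(x[(-lag_n + 1L):n], rep(x[n], -lag_n))
}

#' Generate a raw multichannel EEG-like signal
#'
#' Produces channels of summed band-limited sinusoids plus broadband
#' Gaussian noise at a raw EEG rate, for exercising the spectral path of
#' the band-energy estimator ([band_energy()]): a band's planted amplitude
#' should surface as elevated mean power in that band's track.
#'
#' @param duration_s Length in seconds.
#' @param rate Sampling rate in Hz (default 256).
#' @param n_channels Number of channels (default 4).
#' @param band_amplitudes Named numeric vector mapping band names from
#'   [band_definitions()] to sinusoid amplitudes (band-center frequencies
#'   are used).
#' @param noise_sd Broadband noise SD (default 1).
#' @param seed Integer seed.
#' @return Numeric matrix (channels x samples) with attribute `"rate"`.
#' @export
gen_raw_eeg <- function(duration_s, rate = 256, n_channels = 4,
                        band_amplitudes = c(Alpha = 2), noise_sd = 1, seed = 1L) {
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1L) / rate
  bd <- band_definitions()
  with_seed(seed, {
    sig <- matrix(rnorm(n_channels * n, sd = noise_sd), nrow = n_channels)
    for (b in names(band_amplitudes)) {
      row <- bd[bd$band == b, ]
      if (nrow(row) != 1L) stop("unknown band: ", b, call. = FALSE)
      f <- (row$lo + row$hi) / 2
      phase <- runif(n_channels, 0, 2 * pi)
      for (ch in seq_len(n_channels)) {
        sig[ch, ] <- sig[ch, ] + band_amplitudes[[b]] * sin(2 * pi * f * t + phase[ch])
      }
    }
    attr(sig, "rate") <- rate
    sig
  })
}
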