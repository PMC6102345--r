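# EEG band-energy pipeline: common-average referencing, sliding-window
# spectral band energy, per-channel z-scoring and electrode-group means.
#
# Inputs are assumed pre-cleaned (line noise and ocular artifacts already
# removed upstream); this module only covers demeaning, referencing and
# the spectral band-energy path.

#' The six analysis frequency bands
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz): Delta (1-4),
#'   Theta (4-7), Alpha (8-15), Beta (15-30), Gamma (30-50) and
#'   HighGamma (70-110).
#' @export
band_definitions <- function() {
  tibble::tibble(
    band = c("Delta", "Theta", "Alpha", "Beta", "Gamma", "HighGamma"),
    lo = c(1, 4, 8, 15, 30, 70),
    hi = c(4, 7, 15, 30, 50, 110)
  )
}

#' Re-reference a multichannel signal to the common average
#'
#' Subtracts the across-channel mean from every channel at each sample,
#' so channel sums are zero per sample.
#'
#' @param signal Numeric matrix, channels x samples (>= 2 channels).
#' @return Matrix of the same shape.
#' @export
rereference_common_average <- function(signal) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 2L) stop("at least 2 channels are required", call. = FALSE)
  sweep(signal, 2L, colMeans(signal))
}

#' Sliding-window band energy, z-scored per channel
#'
#' Power spectra are taken over Hann-tapered sliding windows (default 1 s
#' length, 100 ms step), averaged over the frequency bins falling in each
#' band, and the resulting per-channel, per-band energy track is z-score
#' normalized over the scene.  Window k starts at `(k-1) * step_s` seconds
#' and windows run while they fit, so a 120 s recording yields 1,191
#' windows at the defaults.
#'
#' @param signal Numeric matrix, channels x samples; rows may be named.
#' @param rate Sampling rate in Hz; must be at least twice the highest
#'   requested band edge (defaults to the `"rate"` attribute of `signal`).
#' @param bands Band table as from [band_definitions()].
#' @param window_s Window length in seconds (default 1).
#' @param step_s Window step in seconds (default 0.1).
#' @param groups Optional named character vector mapping channel names to
#'   electrode groups (e.g. `"frontal"`, `"central"`).
#' @param demean Subtract each channel's mean first (default TRUE).
#' @return A long tibble (`channel`, `band`, `time`, `energy`) at
#'   `1/step_s` Hz; `time` is the window start.  Attributes: `"rate"`,
#'   `"groups"`, and `"raw_power"` (the pre-z-scored band power, same row
#'   order) for spectral checks.
#' @export
band_energy <- function(signal, rate = NULL, bands = band_definitions(),
                        window_s = 1, step_s = 0.1, groups = NULL,
                        demean = TRUE) {
  signal <- as.matrix(signal)
  if (is.null(rate)) rate <- attr(signal, "rate")
  if (is.null(rate)) stop("`rate` must be supplied", call. = FALSE)
  too_high <- bands$hi > rate / 2
  if (any(too_high)) {
    stop("sampling rate ", rate, " Hz is too low for band(s): ",
         paste(bands$band[too_high], collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(signal))) {
    rownames(signal) <- sprintf("ch%02d", seq_len(nrow(signal)))
  }
  if (demean) signal <- signal - rowMeans(signal)
  n <- ncol(signal)
  dur <- n / rate
  win_n <- round(window_s * rate)
  n_win <- floor((dur - window_s) / step_s) + 1L
  if (n_win < 2L) stop("signal shorter than two analysis windows", call. = FALSE)
  starts <- round((seq_len(n_win) - 1L) * step_s * rate) + 1L
  starts <- pmin(starts, n - win_n + 1L)
  taper <- hann_window(win_n)
  freqs <- (seq_len(win_n %/% 2L + 1L) - 1L) * rate / win_n
  bin_sets <- lapply(seq_len(nrow(bands)), function(b) {
    which(freqs >= bands$lo[b] & freqs <= bands$hi[b])
  })
  times <- (starts - 1L) / rate
  rows <- vector("list", nrow(signal) * nrow(bands))
  k <- 0L
  for (ch in seq_len(nrow(signal))) {
    # all windows of this channel as one matrix -> one mvfft call
    wmat <- matrix(0, nrow = win_n, ncol = n_win)
    for (j in seq_len(n_win)) {
      wmat[, j] <- signal[ch, starts[j]:(starts[j] + win_n - 1L)] * taper
    }
    pw <- Mod(stats::mvfft(wmat)[seq_len(win_n %/% 2L + 1L), , drop = FALSE])^2
    for (b in seq_len(nrow(bands))) {
      raw <- colMeans(pw[bin_sets[[b]], , drop = FALSE])
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        channel = rownames(signal)[ch], band = bands$band[b],
        time = times, energy = zscore(raw), raw_power = raw
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  raw_power <- out$raw_power
  out$raw_power <- NULL
  attr(out, "raw_power") <- raw_power
  attr(out, "rate") <- 1 / step_s
  attr(out, "groups") <- groups
  out
}

#' Average band-energy tracks over an electrode group
#'
#' @param series Long band-energy tibble from [band_energy()] or
#'   [gen_band_energy()] (with a `"groups"` attribute or `groups` given).
#' @param group Group name, or `"all"` for a grand average.
#' @param groups Optional named character vector overriding the attribute.
#' @return A tibble (`band`, `time`, `energy`) averaged over the group's
#'   channels, with attribute `"rate"` carried through.
#' @export
group_average <- function(series, group = "all", groups = NULL) {
  if (is.null(groups)) groups <- attr(series, "groups")
  if (identical(group, "all")) {
    keep <- unique(series$channel)
  } else {
    if (is.null(groups)) stop("no group labels available", call. = FALSE)
    keep <- names(groups)[groups == group]
  }
  if (length(keep) == 0L) stop("electrode group '", group, "' is empty", call. = FALSE)
  out <- series |>
    dplyr::filter(.data$channel %in% keep) |>
    dplyr::group_by(.data$band, .data$time) |>
    dplyr::summarise(energy = mean(.data$energy), .groups = "drop")
  attr(out, "rate") <- attr(series, "rate")
  out
}
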