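# Log-mel spectrogram front end for the audio CNN.
#
# Audio is resampled internally to a single analysis rate (16 kHz) so that
# the 25 ms window / 10 ms hop framing uses integer sample counts (400/160)
# and scenes recorded at 22,050 Hz or synthetic rates behave identically.

MEL_ANALYSIS_RATE <- 16000L
MEL_WIN <- 400L       # 25 ms
MEL_HOP <- 160L       # 10 ms
MEL_NFFT <- 512L
MEL_N_BANDS <- 64L
MEL_FMIN <- 125
MEL_FMAX <- 7500
MEL_LOG_FLOOR <- 1e-10

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# 64 triangular filters on the mel scale between MEL_FMIN and MEL_FMAX,
# acting on the one-sided power spectrum of an MEL_NFFT-point FFT.
mel_filterbank <- function() {
  n_bins <- MEL_NFFT %/% 2L + 1L
  bin_freq <- (seq_len(n_bins) - 1L) * MEL_ANALYSIS_RATE / MEL_NFFT
  edges <- mel_to_hz(seq(hz_to_mel(MEL_FMIN), hz_to_mel(MEL_FMAX),
                         length.out = MEL_N_BANDS + 2L))
  fb <- matrix(0, nrow = n_bins, ncol = MEL_N_BANDS)
  for (b in seq_len(MEL_N_BANDS)) {
    lo <- edges[b]; mid <- edges[b + 1L]; hi <- edges[b + 2L]
    up <- (bin_freq - lo) / (mid - lo)
    down <- (hi - bin_freq) / (hi - mid)
    fb[, b] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Compute the log-mel spectrogram of a scene
#'
#' The CNN front end: 25 ms Hann windows advanced in 10 ms steps, 64
#' mel-spaced bands.  The framing convention is chosen so that a 960 ms
#' segment yields exactly 96 frames: the number of frames is
#' `floor(n_samples / hop)` at the 16 kHz analysis rate, with half-window
#' reflection padding so windows are centered near their nominal times.
#'
#' @param scene An `audio_scene` (any sample rate; resampled internally to
#'   16 kHz) or a numeric vector with `rate` given.
#' @param rate Sampling rate in Hz when `scene` is a bare vector.
#' @return An object of class `mel_spectrogram`: list with `values`
#'   (frames x 64 matrix of natural-log mel power, floored at 1e-10),
#'   `frame_hop_s` (0.010), `window_s` (0.025) and `frame_rate` (100).
#' @examples
#' seg <- audio_scene(sin(2 * pi * 440 * (0:15359) / 16000), 16000)
#' dim(compute_mel_spectrogram(seg)$values)  # 96 x 64
#' @export
compute_mel_spectrogram <- function(scene, rate = NULL) {
  if (inherits(scene, "audio_scene")) {
    x <- scene$samples
    rate <- scene$sample_rate
  } else {
    x <- as.numeric(scene)
    if (is.null(rate)) stop("`rate` must be given for a bare vector", call. = FALSE)
  }
  if (length(x) / rate < MEL_WIN / MEL_ANALYSIS_RATE) {
    stop("scene shorter than one analysis window (25 ms)", call. = FALSE)
  }
  if (rate != MEL_ANALYSIS_RATE) {
    x <- resample_linear(x, rate, MEL_ANALYSIS_RATE)
  }
  n <- length(x)
  n_frames <- n %/% MEL_HOP
  if (n_frames < 1L) stop("scene shorter than one hop", call. = FALSE)
  half <- MEL_WIN %/% 2L
  # reflect-pad half a window at each end; frame k starts at (k-1)*hop on
  # the padded signal
  pad <- c(rev(x[2:(half + 1L)]), x, rev(x[(n - half):(n - 1L)]))
  need <- (n_frames - 1L) * MEL_HOP + MEL_WIN
  if (need > length(pad)) pad <- c(pad, rep(0, need - length(pad)))
  win <- hann_window(MEL_WIN)
  starts <- (seq_len(n_frames) - 1L) * MEL_HOP
  frames <- matrix(0, nrow = MEL_NFFT, ncol = n_frames)
  idx <- seq_len(MEL_WIN)
  for (k in seq_len(n_frames)) {
    frames[idx, k] <- pad[starts[k] + idx] * win
  }
  spec <- stats::mvfft(frames)
  power <- Mod(spec[seq_len(MEL_NFFT %/% 2L + 1L), , drop = FALSE])^2
  mel_power <- crossprod(power, mel_filterbank())     # frames x bands
  values <- log(pmax(mel_power, MEL_LOG_FLOOR))
  structure(
    list(values = values, frame_hop_s = MEL_HOP / MEL_ANALYSIS_RATE,
         window_s = MEL_WIN / MEL_ANALYSIS_RATE,
         frame_rate = MEL_ANALYSIS_RATE / MEL_HOP),
    class = "mel_spectrogram"
  )
}

#' @export
print.mel_spectrogram <- function(x, ...) {
  cat(sprintf("<mel_spectrogram> %d frames x %d bands (hop %.0f ms)\n",
              nrow(x$values), ncol(x$values), 1000 * x$frame_hop_s))
  invisible(x)
}
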