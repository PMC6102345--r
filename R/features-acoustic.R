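# The ten acoustic feature tracks.
#
# The analyses use standard definitions of the named quantities: loudness
# is frame RMS in dB, brightness the spectral centroid, bandwidth the
# spectral spread, flatness the geometric/arithmetic spectral-mean ratio,
# irregularity the normalized sum of squared successive spectral-bin
# differences, pitch the autocorrelation peak in 50-2000 Hz, harmonicity
# that peak's normalized height, and rate/scale the energy centroids of
# the temporal- and spectral-modulation spectra of the log-mel
# spectrogram.  Roughness is the average magnitude of 30-150 Hz amplitude
# modulations normalized by frame RMS.

ROUGHNESS_BAND <- c(30, 150)

#' Compute a roughness track for a scene
#'
#' Roughness is the average magnitude of temporal (amplitude) modulations
#' between 30 and 150 Hz, normalized by the root-mean-squared energy of
#' the frame.  Per frame the amplitude envelope is extracted as the
#' magnitude of the analytic signal (Hilbert), mean-removed, and its DFT
#' magnitude averaged over bins in 30-150 Hz, then divided by the frame
#' RMS (so the measure is invariant to overall amplitude).  Silent frames
#' (zero RMS) have roughness 0 by definition.
#'
#' @param scene An `audio_scene` or numeric vector.
#' @param frame_s Frame length in seconds; must be at least 0.1 s so a
#'   30 Hz modulation is resolvable (default 0.5).
#' @param hop_s Hop between frames (default `frame_s`, i.e. non-overlapping).
#' @param rate Sampling rate when `scene` is a bare vector.
#' @return A tibble with columns `time` (frame start, s) and `roughness`,
#'   with attribute `"rate"` set to `1 / hop_s`.
#' @export
compute_roughness <- function(scene, frame_s = 0.5, hop_s = frame_s, rate = NULL) {
  if (inherits(scene, "audio_scene")) {
    x <- scene$samples
    rate <- scene$sample_rate
  } else {
    x <- as.numeric(scene)
    if (is.null(rate)) stop("`rate` must be given for a bare vector", call. = FALSE)
  }
  if (frame_s < 0.1) {
    stop("`frame_s` must be at least 0.1 s to resolve a 30 Hz modulation",
         call. = FALSE)
  }
  frame_n <- round(frame_s * rate)
  hop_n <- max(1L, round(hop_s * rate))
  n_frames <- (length(x) - frame_n) %/% hop_n + 1L
  if (n_frames < 1L) stop("scene shorter than one roughness frame", call. = FALSE)
  freqs <- (seq_len(frame_n) - 1L) / frame_s
  band <- which(freqs >= ROUGHNESS_BAND[1] & freqs <= ROUGHNESS_BAND[2])
  vals <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    fr <- x[((k - 1L) * hop_n + 1L):((k - 1L) * hop_n + frame_n)]
    rms <- sqrt(mean(fr^2))
    if (rms == 0) { vals[k] <- 0; next }
    env <- analytic_envelope(fr)
    env <- env - mean(env)
    mag <- Mod(fft(env)) / frame_n
    vals[k] <- mean(mag[band]) / rms
  }
  out <- tibble::tibble(time = (seq_len(n_frames) - 1L) * hop_n / rate,
                        roughness = vals)
  attr(out, "rate") <- rate / hop_n
  out
}

#' Compute the ten acoustic feature tracks of a scene
#'
#' Returns loudness, brightness, bandwidth, flatness, irregularity, pitch,
#' harmonicity, rate, scale and roughness at a common frame rate (default
#' 10 Hz, from 0.2 s windows advanced by 0.1 s).  See the package
#' vignette for the exact definitions.
#'
#' @param scene An `audio_scene` or numeric vector.
#' @param window_s Analysis window in seconds (default 0.2).
#' @param hop_s Hop between frames in seconds (default 0.1).
#' @param rate Sampling rate when `scene` is a bare vector.
#' @return A tibble with a `time` column (frame start, s) and one column
#'   per feature, all the same length; attribute `"rate"` is `1 / hop_s`.
#' @export
compute_acoustic_features <- function(scene, window_s = 0.2, hop_s = 0.1,
                                      rate = NULL) {
  if (inherits(scene, "audio_scene")) {
    x <- scene$samples
    rate <- scene$sample_rate
  } else {
    x <- as.numeric(scene)
    if (is.null(rate)) stop("`rate` must be given for a bare vector", call. = FALSE)
  }
  win_n <- round(window_s * rate)
  hop_n <- round(hop_s * rate)
  n_frames <- (length(x) - win_n) %/% hop_n + 1L
  if (n_frames < 1L) stop("scene shorter than one analysis window", call. = FALSE)
  win <- hann_window(win_n)
  freqs <- (seq_len(win_n %/% 2L) - 1L) * rate / win_n
  lag_lo <- max(2L, floor(rate / 2000))        # pitch search 50-2000 Hz
  lag_hi <- min(win_n - 1L, ceiling(rate / 50))

  loudness <- brightness <- bandwidth <- flatness <- numeric(n_frames)
  irregularity <- pitch <- harmonicity <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    fr <- x[((k - 1L) * hop_n + 1L):((k - 1L) * hop_n + win_n)]
    rms <- sqrt(mean(fr^2))
    loudness[k] <- 20 * log10(max(rms, 1e-10))
    mag <- Mod(fft(fr * win))[seq_len(win_n %/% 2L)]
    p <- mag^2
    tot <- sum(p)
    if (tot <= 0) {
      brightness[k] <- 0; bandwidth[k] <- 0; flatness[k] <- 1
      irregularity[k] <- 0; pitch[k] <- 0; harmonicity[k] <- 0
      next
    }
    brightness[k] <- sum(freqs * p) / tot
    bandwidth[k] <- sqrt(sum((freqs - brightness[k])^2 * p) / tot)
    flatness[k] <- exp(mean(log(p + 1e-12))) / mean(p + 1e-12)
    irregularity[k] <- sum(diff(mag)^2) / sum(mag^2)
    # autocorrelation via FFT (zero-padded to avoid circular wrap)
    nfft <- 2L * win_n
    ac <- Re(fft(Mod(fft(c(fr, numeric(nfft - win_n))))^2, inverse = TRUE))[1:win_n]
    if (ac[1L] > 0 && lag_hi > lag_lo) {
      seg <- ac[(lag_lo + 1L):(lag_hi + 1L)] / ac[1L]
      i_max <- which.max(seg)
      pitch[k] <- rate / (lag_lo + i_max - 1L)
      harmonicity[k] <- max(0, seg[i_max])
    }
  }

  mel <- compute_mel_spectrogram(x, rate = rate)
  ms <- modulation_centroids(mel, n_frames, hop_s)
  rough <- compute_roughness(x, frame_s = max(window_s, 0.1), hop_s = hop_s,
                             rate = rate)$roughness
  rough <- pad_to(rough, n_frames)

  out <- tibble::tibble(
    time = (seq_len(n_frames) - 1L) * hop_s,
    loudness = loudness, brightness = brightness, bandwidth = bandwidth,
    flatness = flatness, irregularity = irregularity, pitch = pitch,
    harmonicity = harmonicity, rate = ms$rate, scale = ms$scale,
    roughness = rough
  )
  attr(out, "rate") <- 1 / hop_s
  out
}

pad_to <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, rep(x[length(x)], n - length(x)))
}

# Temporal- and spectral-modulation energy centroids of the log-mel
# spectrogram, evaluated on 320 ms patches centered on each feature frame.
modulation_centroids <- function(mel, n_frames, hop_s) {
  v <- mel$values                       # mel frames x 64
  n_mel <- nrow(v)
  patch <- 32L                          # 320 ms of 10 ms mel frames
  mel_per_hop <- hop_s * mel$frame_rate
  rate_freqs <- (seq_len(patch %/% 2L) - 1L) * mel$frame_rate / patch
  scale_freqs <- (seq_len(ncol(v) %/% 2L) - 1L) / ncol(v)   # cycles/band
  rate_c <- scale_c <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    c0 <- round((k - 1L) * mel_per_hop) + 1L
    i0 <- max(1L, min(c0, n_mel - patch + 1L))
    p <- v[i0:min(i0 + patch - 1L, n_mel), , drop = FALSE]
    if (nrow(p) < patch) p <- rbind(p, matrix(p[nrow(p), ], patch - nrow(p), ncol(p), byrow = TRUE))
    p <- sweep(p, 2L, colMeans(p))
    tm <- Mod(stats::mvfft(p))[seq_along(rate_freqs), , drop = FALSE]
    wt <- rowSums(tm^2)
    rate_c[k] <- if (sum(wt) > 0) sum(rate_freqs * wt) / sum(wt) else 0
    q <- p - rowMeans(p)
    sm <- Mod(stats::mvfft(t(q)))[seq_along(scale_freqs), , drop = FALSE]
    ws <- rowSums(sm^2)
    scale_c[k] <- if (sum(ws) > 0) sum(scale_freqs * ws) / sum(ws) else 0
  }
  list(rate = rate_c, scale = scale_c)
}

#' Write a ten-feature table as tab-separated text
#'
#' Convenience wrapper around [write_track_table()] that checks the ten
#' feature tracks are present.
#'
#' @param features Output of [compute_acoustic_features()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  needed <- c("loudness", "brightness", "bandwidth", "flatness", "irregularity",
              "pitch", "harmonicity", "rate", "scale", "roughness")
  missing <- setdiff(needed, names(features))
  if (length(missing)) stop("missing feature track(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  write_track_table(features, path)
}
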