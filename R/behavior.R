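# Behavioral salience: percentage-attending curves and salient events.

#' Salience curve from a subject-by-time attention matrix
#'
#' Salience is the percentage of subjects attending to the scene at each
#' time sample: the column mean of the binary attention matrix times 100.
#'
#' @param attention Binary matrix, subjects x time samples (entries 0/1).
#' @param rate Sampling rate of the columns in Hz (default 10).
#' @return A tibble with columns `time` and `percent` (in \[0, 100\]),
#'   attribute `"rate"`.
#' @export
salience_from_attention <- function(attention, rate = 10) {
  attention <- as.matrix(attention)
  if (nrow(attention) < 2L) stop("at least 2 subjects are required", call. = FALSE)
  if (!is_binary(attention)) stop("attention entries must be 0 or 1", call. = FALSE)
  out <- tibble::tibble(
    time = (seq_len(ncol(attention)) - 1L) / rate,
    percent = 100 * colMeans(attention)
  )
  attr(out, "rate") <- rate
  out
}

#' Detect salient events from a salience curve
#'
#' Salient events are peaks in the (smoothed) derivative of the salience
#' curve: moments when many subjects begin attending together.  The
#' derivative is smoothed with the same three-pass moving average used for
#' feature slopes ([feature_slope()]).  Local maxima below
#' `noise_floor_sd` times the derivative's standard deviation are ignored.
#' Each surviving candidate's strength is an equally weighted sum of the
#' z-scored slope height and the z-scored maximum of the curve within the
#' 4 s window following the event; the strongest `keep_fraction` of
#' candidates are kept.
#'
#' @param curve A salience tibble (`time`, `percent`) from
#'   [gen_salience()] / [salience_from_attention()], or a numeric vector.
#' @param rate Curve sampling rate in Hz (default 10, or the `"rate"`
#'   attribute).
#' @param keep_fraction Fraction of candidates retained, strongest first
#'   (default 0.5; the kept count is `ceiling(keep_fraction * n)`).
#' @param noise_floor_sd Candidate threshold in derivative SD units
#'   (default 0.5).
#' @param slope_weight,peak_weight Weights of the two z-scored strength
#'   components (default 1 and 1).
#' @param ma_window,ma_passes Smoother settings passed to
#'   [feature_slope()] (defaults 5 samples, 3 passes).
#' @param annotations Optional ground-truth annotation tibble (with
#'   `onset_s`, `category`); each event is assigned the category of the
#'   nearest annotation, otherwise `"other"`.
#' @return A tibble of events: `time_s`, `strength`, `category`, sorted by
#'   time, with the full candidate set in attribute `"candidates"`.
#' @export
detect_salient_events <- function(curve, rate = NULL, keep_fraction = 0.5,
                                  noise_floor_sd = 0.5,
                                  slope_weight = 1, peak_weight = 1,
                                  ma_window = 5L, ma_passes = 3L,
                                  annotations = NULL) {
  if (is.data.frame(curve)) {
    if (is.null(rate)) rate <- attr(curve, "rate")
    values <- curve$percent
  } else {
    values <- as.numeric(curve)
  }
  if (is.null(rate)) rate <- 10
  if (length(values) / rate < 10) stop("curve must be at least 10 s long", call. = FALSE)
  d <- feature_slope(values, rate = rate, ma_window = ma_window,
                     ma_passes = ma_passes)
  n <- length(d)
  floor_val <- noise_floor_sd * sd(d)
  is_peak <- c(FALSE, d[2:(n - 1L)] > d[1:(n - 2L)] & d[2:(n - 1L)] >= d[3:n], FALSE)
  cand <- which(is_peak & d > floor_val & d > 0)
  if (length(cand) == 0L) {
    out <- tibble::tibble(time_s = numeric(), strength = numeric(),
                          category = character())
    attr(out, "candidates") <- out
    return(out)
  }
  times <- (cand - 1L) / rate
  slope_h <- d[cand]
  win_n <- round(4 * rate)
  peak_h <- vapply(cand, function(i) max(values[i:min(i + win_n, length(values))]),
                   numeric(1))
  strength <- slope_weight * zscore(slope_h) + peak_weight * zscore(peak_h)
  cats <- rep("other", length(cand))
  if (!is.null(annotations) && nrow(annotations) > 0) {
    cats <- vapply(times, function(t) {
      annotations$category[which.min(abs(annotations$onset_s - t))]
    }, character(1))
  }
  candidates <- tibble::tibble(time_s = times, strength = strength, category = cats)
  n_keep <- ceiling(keep_fraction * nrow(candidates))
  out <- candidates |>
    dplyr::arrange(dplyr::desc(.data$strength)) |>
    head(n_keep) |>
    dplyr::arrange(.data$time_s)
  attr(out, "candidates") <- candidates
  out
}
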