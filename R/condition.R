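# Common signal conditioning and lagged correlation.
#
# Every continuous signal entering a correlation (surprisal, acoustic
# feature, salience, band energy) passes through the same chain: resample
# to 10 Hz, truncate to at most 120 s, drop the first 2 s (trial onset),
# then band-limit to [1/30, 1/6] Hz with fourth-order Butterworth filters
# applied forward-backward (zero phase), so filtering adds no hidden lag.

# Direct-form II transposed IIR filter with explicit initial state.
iir_filter <- function(b, a, x, zi) {
  n <- length(x)
  nf <- length(b)
  z <- zi
  y <- numeric(n)
  for (i in seq_len(n)) {
    y[i] <- b[1L] * x[i] + z[1L]
    if (nf > 2L) {
      for (j in seq_len(nf - 2L)) {
        z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * y[i]
      }
    }
    z[nf - 1L] <- b[nf] * x[i] - a[nf] * y[i]
  }
  y
}

# Steady-state initial filter state for a unit-amplitude step input, so a
# constant signal passes through transient-free.
filter_zi <- function(b, a) {
  nf <- length(a)
  comp <- matrix(0, nf - 1L, nf - 1L)
  comp[1L, ] <- -a[-1L] / a[1L]
  if (nf > 2L) comp[cbind(2:(nf - 1L), 1:(nf - 2L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(nf - 1L) - t(comp), B)
}

# Extend a series `n_ahead` samples beyond its end by autoregressive
# (Burg) prediction; falls back to holding the end value.  Sinusoids and
# constants extend exactly, so filter pads built this way carry no
# spurious step or trend for the filter to respond to.
ar_extend <- function(x, n_ahead) {
  fit <- tryCatch(
    stats::ar(x, method = "burg",
              order.max = min(20L, max(1L, floor(length(x) / 3)))),
    error = function(e) NULL)
  if (is.null(fit) || fit$order == 0L || any(!is.finite(fit$ar))) {
    return(rep(x[length(x)], n_ahead))
  }
  p <- fit$order
  co <- fit$ar
  buf <- c(utils::tail(x, p) - fit$x.mean, numeric(n_ahead))
  for (i in seq_len(n_ahead)) {
    buf[p + i] <- sum(co * buf[(p + i - 1L):i])
  }
  fit$x.mean + buf[(p + 1L):(p + n_ahead)]
}

# Zero-phase (forward-backward) filtering with AR-extension end padding
# and steady-state initial conditions, so edge transients stay negligible
# even for cutoffs far below the signal length scale.
zero_phase_filter <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  if (length(b) < length(a)) b <- c(b, numeric(length(a) - length(b)))
  if (length(a) < length(b)) a <- c(a, numeric(length(b) - length(a)))
  n <- length(x)
  # pad long enough for the slowest pole's transient to decay to 0.1%
  r <- max(Mod(polyroot(rev(a))))
  padlen <- if (r < 1) ceiling(log(1e-3) / log(r)) else n - 1L
  padlen <- max(3L * (length(a) - 1L), min(n - 1L, padlen))
  ext <- c(rev(ar_extend(rev(x), padlen)), x, ar_extend(x, padlen))
  zi <- filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1L])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Condition a time series for the correlation analyses
#'
#' @param x Numeric series, or a tibble with a value column (the first
#'   non-`time` numeric column is used).
#' @param rate Input sampling rate in Hz; defaults to the `"rate"`
#'   attribute of `x` if present.
#' @param target_rate Output rate (default 10 Hz).
#' @param trim_s Seconds removed from the start after truncation
#'   (default 2).
#' @param max_total_s Maximum length before trimming (default 120 s, so
#'   at most 118 s survive).
#' @param band High-pass and low-pass cutoffs in Hz
#'   (default `c(1/30, 1/6)`).
#' @param origin Optional origin label (`"surprisal"`, `"feature"`,
#'   `"salience"`, `"band"`), stored as an attribute.
#' @return Numeric vector at `target_rate` with attributes `"rate"` and
#'   `"origin"`.
#' @export
condition_series <- function(x, rate = NULL, target_rate = 10, trim_s = 2,
                             max_total_s = 120, band = c(1 / 30, 1 / 6),
                             origin = NULL) {
  if (is.data.frame(x)) {
    if (is.null(rate)) rate <- attr(x, "rate")
    value_col <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], "time")[1]
    x <- x[[value_col]]
  }
  if (is.null(rate)) rate <- attr(x, "rate")
  if (is.null(rate)) stop("`rate` must be supplied", call. = FALSE)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  if (length(x) / rate < 5) stop("series must be at least 5 s long", call. = FALSE)
  y <- if (rate == target_rate) x else resample_linear(x, rate, target_rate)
  n_max <- round(max_total_s * target_rate)
  if (length(y) > n_max) y <- y[seq_len(n_max)]
  n_trim <- round(trim_s * target_rate)
  if (n_trim > 0) y <- y[-seq_len(n_trim)]
  nyq <- target_rate / 2
  hp <- signal::butter(4, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  y <- zero_phase_filter(hp, y)
  y <- zero_phase_filter(lp, y)
  attr(y, "rate") <- target_rate
  attr(y, "origin") <- origin
  y
}

#' Maximum lagged normalized correlation between two series
#'
#' Computes the Pearson correlation between `x` and `y` at every integer-
#' sample lag within `max_lag_s` seconds, on the overlapping region of
#' each shift, and returns the maximum together with its lag.  A positive
#' lag means `y` follows `x` (i.e. `y` is delayed relative to `x`).
#'
#' @param x,y Numeric series at the same rate (typically conditioned with
#'   [condition_series()]).
#' @param rate Sampling rate in Hz (default 10, or the `"rate"` attribute
#'   of `x`).
#' @param max_lag_s Maximum absolute lag searched, in seconds (default 3).
#' @return A one-row tibble with columns `r` and `lag_s`; `r` is `NA` with
#'   a warning if any overlap has zero variance.
#' @export
max_lagged_correlation <- function(x, y, rate = NULL, max_lag_s = 3) {
  if (is.null(rate)) rate <- attr(x, "rate")
  if (is.null(rate)) rate <- 10
  x <- as.numeric(x); y <- as.numeric(y)
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  max_lag <- round(max_lag_s * rate)
  if (n - max_lag < 10 * rate) {
    stop("series overlap must be at least 10 s at every admissible lag",
         call. = FALSE)
  }
  lags <- (-max_lag):max_lag
  rs <- vapply(lags, function(L) {
    if (L >= 0) {
      xs <- x[seq_len(n - L)]; ys <- y[(1L + L):n]
    } else {
      xs <- x[(1L - L):n]; ys <- y[seq_len(n + L)]
    }
    if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys)
  }, numeric(1))
  if (all(is.na(rs))) {
    warning("zero-variance overlap at every lag; correlation undefined")
    return(tibble::tibble(r = NA_real_, lag_s = NA_real_))
  }
  if (any(is.na(rs))) warning("zero-variance overlap at some lags")
  best <- which.max(rs)
  tibble::tibble(r = rs[best], lag_s = lags[best] / rate)
}

#' Correlation between surprisal and salience in windows around events
#'
#' For each salient event at time t, correlates the surprisal series over
#' \[t - half_window_s, t + half_window_s\] with the salience series over
#' the same window shifted by `delay_s` (the fixed motor-response delay of
#' the behavioral report, default 1.4 s).  Events whose window would
#' exceed either series are skipped and counted.
#'
#' @param surprisal,salience Conditioned numeric series at a common rate.
#' @param events Tibble of salient events with a `time_s` column (e.g.
#'   from [detect_salient_events()]), or a numeric vector of event times.
#' @param rate Sampling rate in Hz (default 10).
#' @param delay_s Salience delay in seconds (default 1.4).
#' @param half_window_s Half window length in seconds (default 3).
#' @return A tibble with one row per included event (`time_s`, `r`), with
#'   attributes `"skipped"` (count) and `"mean_r"`.
#' @export
windowed_event_correlation <- function(surprisal, salience, events, rate = NULL,
                                       delay_s = 1.4, half_window_s = 3) {
  if (is.null(rate)) rate <- attr(surprisal, "rate")
  if (is.null(rate)) rate <- 10
  times <- if (is.data.frame(events)) events$time_s else as.numeric(events)
  surprisal <- as.numeric(surprisal); salience <- as.numeric(salience)
  half_n <- round(half_window_s * rate)
  delay_n <- round(delay_s * rate)
  skipped <- 0L
  rows <- list()
  for (t_ev in times) {
    c_idx <- round(t_ev * rate) + 1L
    s_lo <- c_idx - half_n; s_hi <- c_idx + half_n
    b_lo <- s_lo + delay_n; b_hi <- s_hi + delay_n
    if (s_lo < 1L || s_hi > length(surprisal) || b_lo < 1L || b_hi > length(salience)) {
      skipped <- skipped + 1L
      next
    }
    a <- surprisal[s_lo:s_hi]
    b <- salience[b_lo:b_hi]
    r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
    rows[[length(rows) + 1L]] <- tibble::tibble(time_s = t_ev, r = r)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(time_s = numeric(), r = numeric())
  attr(out, "skipped") <- skipped
  attr(out, "mean_r") <- if (nrow(out)) mean(out$r, na.rm = TRUE) else NA_real_
  out
}
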