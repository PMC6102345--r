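# Internal numeric helpers shared across modules.

# Run `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# Linear-interpolation resampling from `rate_in` to `rate_out`.
# Sample k (1-based) of the output sits at time (k-1)/rate_out; output
# covers the same span as the input, never extrapolating.
resample_linear <- function(x, rate_in, rate_out) {
  n <- length(x)
  if (n < 2L) stop("series too short to resample", call. = FALSE)
  t_in <- (seq_len(n) - 1L) / rate_in
  t_out <- seq(0, t_in[n], by = 1 / rate_out)
  approx(t_in, x, xout = t_out, rule = 1L)$y
}

# Magnitude of the analytic signal (discrete Hilbert transform via FFT).
analytic_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# Centered equally weighted moving average with shrinking windows at the
# edges (the mean is taken over the samples actually available).
moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# 1/f ("pink") noise with unit RMS, generated by spectral shaping of white
# Gaussian noise: amplitude scaled by 1/sqrt(f).
pink_noise <- function(n) {
  white <- rnorm(n)
  X <- fft(white)
  k <- c(1, seq_len(n - 1L))       # avoid division by zero at DC
  scale <- 1 / sqrt(pmin(k, n - k + 1))
  scale[1L] <- 0                    # remove DC
  y <- Re(fft(X * scale, inverse = TRUE) / n)
  y / sd(y)
}

# Hann window (periodic form, as used in streaming STFT front ends).
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

# z-score with a guard for zero spread.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

is_binary <- function(x) all(x %in% c(0, 1))
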