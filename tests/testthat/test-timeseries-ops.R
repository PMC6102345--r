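# Signal conditioning and lagged correlation.

test_that("conditioning rejects DC and attenuates above the low-pass band", {
  dc <- condition_series(rep(5, 1300), rate = 10)
  expect_lt(max(abs(dc)), 0.01 * 5)                    # > 99% DC rejection
  t <- (0:1299) / 10
  s <- sin(2 * pi * 0.5 * t)
  out <- condition_series(s, rate = 10)
  in_rms <- sqrt(mean(s^2))
  # Butterworth magnitude oracle: order-4 low pass at 1/6 Hz applied
  # forward-backward gives |H|^2 = 1/(1 + (f/fc)^8) at f = 0.5 Hz
  oracle_gain <- 1 / (1 + (0.5 / (1 / 6))^8)
  expect_lt(sqrt(mean(out^2)) / in_rms, 0.02)
  expect_lt(sqrt(mean(out^2)) / in_rms, 5 * oracle_gain + 0.01)
})

test_that("conditioning trims, truncates and resamples to the documented length", {
  out <- condition_series(rnorm(1300), rate = 10)      # 130 s at 10 Hz
  expect_length(out, 1180L)                            # (120 - 2) * 10
  out2 <- condition_series(rnorm(130 * 44100), rate = 44100)
  expect_length(out2, 1180L)
  short <- condition_series(rnorm(100), rate = 10)     # 10 s input
  expect_length(short, 80L)
  expect_error(condition_series(rnorm(30), rate = 10), "5 s")
  expect_error(condition_series(c(rnorm(99), NA), rate = 10), "finite")
})

test_that("conditioning an already-conditioned in-band signal is near-idempotent", {
  # idempotence holds for in-band content; energy on the Butterworth
  # shoulders is attenuated again on every pass (documented limitation)
  t <- (0:1299) / 10
  x <- sin(2 * pi * 0.06 * t) + 0.5 * sin(2 * pi * 0.1 * t + 1)
  y1 <- condition_series(x, rate = 10)
  y2 <- condition_series(as.numeric(y1), rate = 10)
  n <- min(length(y1), length(y2))
  rms1 <- sqrt(mean(y1[seq_len(n)]^2)); rms2 <- sqrt(mean(y2[seq_len(n)]^2))
  expect_lt(abs(rms2 - rms1) / rms1, 0.05)
})

test_that("lagged correlation finds identity and planted lags", {
  x <- conditioned_noise(1300)
  expect_equal(max_lagged_correlation(x, x, rate = 10),
               tibble::tibble(r = 1, lag_s = 0))
  set.seed(21)
  lag_n <- 12                                          # 1.2 s
  y <- c(rep(x[1], lag_n), head(as.numeric(x), -lag_n)) + rnorm(length(x), sd = 0.05 * sd(x))
  res <- max_lagged_correlation(x, y, rate = 10)
  expect_lte(abs(res$lag_s - 1.2), 0.1)
  expect_gt(res$r, 0.95)
})

test_that("swapping the inputs negates the lag but keeps the correlation", {
  set.seed(22)
  x <- conditioned_noise()
  y <- shift <- c(rep(x[1], 7), head(as.numeric(x), -7)) + rnorm(length(x), sd = 0.1 * sd(x))
  a <- max_lagged_correlation(x, y, rate = 10)
  b <- max_lagged_correlation(y, x, rate = 10)
  expect_equal(a$r, b$r, tolerance = 1e-10)
  expect_equal(a$lag_s, -b$lag_s)
})

test_that("independent band-limited noise stays far below planted-lag correlations", {
  # null calibration: with zero-phase (squared-magnitude) band limiting to
  # [1/30, 1/6] Hz a 118 s series has ~30 effective samples, so the max
  # over 61 lags of a null correlation sits near 0.2 with a 95th
  # percentile near 0.4 -- far below the r > 0.95 planted-lag regime
  set.seed(33)
  null_r <- vapply(1:200, function(i) {
    x <- conditioned_noise()
    y <- conditioned_noise()
    max_lagged_correlation(x, y, rate = 10)$r
  }, numeric(1))
  expect_lt(stats::median(null_r), 0.25)
  expect_lt(stats::quantile(null_r, 0.95), 0.5)
  expect_gte(mean(null_r < 0.35), 0.85)
})

test_that("too-short overlap and zero variance are flagged", {
  expect_error(max_lagged_correlation(rnorm(50), rnorm(50), rate = 10), "10 s")
  expect_warning(res <- max_lagged_correlation(rep(1, 200), rnorm(200), rate = 10),
                 "zero-variance")
  expect_true(is.na(res$r))
})

test_that("event-window correlation is exact for a delayed copy", {
  x <- as.numeric(conditioned_noise())
  delay_n <- 14                                        # 1.4 s at 10 Hz
  sal <- c(rep(0, delay_n), head(x, -delay_n))
  events <- tibble::tibble(time_s = c(20, 40, 60))
  res <- windowed_event_correlation(x, sal, events, rate = 10, delay_s = 1.4)
  expect_equal(nrow(res), 3L)
  expect_equal(res$r, rep(1, 3), tolerance = 1e-10)
  expect_equal(attr(res, "skipped"), 0L)
})

test_that("event-window correlation skips out-of-bounds events and handles none", {
  x <- as.numeric(conditioned_noise())
  res <- windowed_event_correlation(x, x, tibble::tibble(time_s = numeric()),
                                    rate = 10)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "skipped"), 0L)
  res2 <- windowed_event_correlation(x, x, c(1, 50, 117.5), rate = 10)
  expect_equal(attr(res2, "skipped"), 2L)
  expect_equal(nrow(res2), 1L)
})

test_that("planted event-locked bumps give a positive mean r under permutation", {
  set.seed(44)
  n <- 1180
  t <- (0:(n - 1)) / 10
  events <- c(15, 35, 55, 75, 95)
  bump <- function(centers) {
    rowSums(vapply(centers, function(c0) exp(-(t - c0)^2 / (2 * 0.8^2)),
                   numeric(n)))
  }
  surp <- bump(events) + rnorm(n, sd = 0.3)
  sal <- bump(events + 1.4) + rnorm(n, sd = 0.3)
  obs <- attr(windowed_event_correlation(surp, sal, events, rate = 10), "mean_r")
  null <- vapply(1:1000, function(i) {
    fake <- runif(5, 5, 110)
    attr(windowed_event_correlation(surp, sal, fake, rate = 10), "mean_r")
  }, numeric(1))
  p <- (1 + sum(null >= obs)) / (1 + length(null))
  expect_lt(p, 0.05)
})
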