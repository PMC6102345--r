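# Synthetic generators: scenes, attention curves, band-energy surrogates.

test_that("scene generation handles the zero case and sizing arithmetic", {
  empty <- tibble::tibble(onset_s = numeric(), category = character(),
                          level_db = numeric(), duration_s = numeric())
  sc <- gen_scene(scene_config(duration_s = 120, event_specs = empty,
                               background_level_db = -Inf, seed = 1))
  expect_length(sc$samples, 2646000L)
  expect_true(all(sc$samples == 0))
})

test_that("scenes are deterministic under a seed and decorrelated across seeds", {
  cfg <- scene_config(duration_s = 10, density = "sparse", seed = 42)
  a <- gen_scene(cfg)
  b <- gen_scene(cfg)
  expect_identical(a$samples, b$samples)
  c <- gen_scene(scene_config(duration_s = 10, density = "sparse", seed = 43))
  expect_lt(abs(cor(a$samples, c$samples)), 0.1)
})

test_that("events beyond the waveform bounds are rejected", {
  bad <- tibble::tibble(onset_s = 9.8, category = "speech",
                        level_db = -10, duration_s = 1)
  expect_error(scene_config(duration_s = 10, event_specs = bad), "bounds")
  expect_error(
    scene_config(duration_s = 10,
                 event_specs = tibble::tibble(onset_s = -1, category = "music",
                                              level_db = -10, duration_s = 0.5)),
    "bounds")
})

test_that("dense scenes have at least 3x the sparse event rate", {
  n_sparse <- nrow(scene_config(duration_s = 60, density = "sparse", seed = 1)$event_specs)
  n_dense <- nrow(scene_config(duration_s = 60, density = "dense", seed = 1)$event_specs)
  expect_gte(n_dense, 3L * n_sparse)
})

test_that("event tokens are acoustically distinct across categories", {
  specs <- tibble::tibble(onset_s = 1, category = EVENT_CATEGORIES[1],
                          level_db = -6, duration_s = 1)
  scenes <- lapply(EVENT_CATEGORIES, function(cat) {
    specs$category <- cat
    gen_scene(scene_config(duration_s = 3, event_specs = specs,
                           background_level_db = -Inf, seed = 9))
  })
  # pairwise waveform correlations of the tokens stay low
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(abs(cor(scenes[[i]]$samples, scenes[[j]]$samples)), 0.5)
  }
})

test_that("attention curves are stationary without event locking", {
  empty <- tibble::tibble(onset_s = numeric(), category = character(),
                          level_db = numeric(), duration_s = numeric())
  sc <- gen_scene(scene_config(duration_s = 60, event_specs = empty, seed = 1))
  # noise threshold for the mean absolute derivative, estimated from seeded
  # null runs (no event gain)
  null_mad <- vapply(1:30, function(s) {
    cur <- gen_salience(sc, subject_model(event_gain = 0, seed = s))
    mean(abs(diff(cur$percent)))
  }, numeric(1))
  threshold <- max(null_mad) * 1.25
  fresh <- gen_salience(sc, subject_model(event_gain = 0, seed = 123))
  expect_lt(mean(abs(diff(fresh$percent))), threshold)
})

test_that("a high-gain event produces a rise within 2 s of event + motor delay", {
  specs <- tibble::tibble(onset_s = 10, category = "speech",
                          level_db = -6, duration_s = 1)
  sc <- gen_scene(scene_config(duration_s = 30, event_specs = specs, seed = 2))
  subj <- subject_model(n_subjects = 50, event_gain = 200, motor_delay_s = 1.4,
                        seed = 5)
  cur <- gen_salience(sc, subj)
  pre <- mean(cur$percent[cur$time >= 8 & cur$time < 10])
  post <- max(cur$percent[cur$time >= 11.4 & cur$time <= 13.4])
  expect_gt(post, pre + 30)
})

test_that("salience curves are percentages and saturate at 100", {
  st <- gen_salience(gen_scene(scene_config(duration_s = 20, seed = 3)),
                     subject_model(seed = 4))
  expect_true(all(st$percent >= 0 & st$percent <= 100))
  all_on <- salience_from_attention(matrix(1L, nrow = 5, ncol = 50))
  expect_true(all(all_on$percent == 100))
})

test_that("subject models with fewer than two subjects are rejected", {
  expect_error(subject_model(n_subjects = 1), "at least 2")
})

test_that("band-energy surrogate reduces to the z-scored driver in the noiseless case", {
  driver <- sin(2 * pi * 0.1 * (0:499) / 10)
  mix <- eeg_mix_config(n_channels = 1, band_weights = c(Delta = 1),
                        planted_lag_s = 0, noise_sd = 0, seed = 1)
  be <- gen_band_energy(driver, mix)
  expect_equal(be$energy, (driver - mean(driver)) / sd(driver), tolerance = 1e-12)
})

test_that("a planted lag is recovered by the lagged-correlation stage", {
  driver <- conditioned_noise(1300)
  mix <- eeg_mix_config(n_channels = 1, band_weights = c(Delta = 1),
                        planted_lag_s = 1.0, noise_sd = 0.2, seed = 7)
  be <- gen_band_energy(as.numeric(driver), mix)
  res <- max_lagged_correlation(as.numeric(driver), be$energy, rate = 10)
  expect_lte(abs(res$lag_s - 1.0), 0.2)
})

test_that("a zero mixing weight leaves no correlation with the driver", {
  set.seed(11)
  driver <- rnorm(1000)
  mix <- eeg_mix_config(n_channels = 1, band_weights = c(Delta = 0),
                        planted_lag_s = 0, noise_sd = 1, seed = 3)
  be <- gen_band_energy(driver, mix)
  for (lag in seq(-3, 3, by = 0.5)) {
    n_shift <- abs(round(lag * 10))
    if (n_shift == 0) {
      expect_lt(abs(cor(driver, be$energy)), 0.2)
    } else {
      expect_lt(abs(cor(head(driver, -n_shift), tail(be$energy, -n_shift))), 0.2)
    }
  }
})

test_that("all three generators are reproducible under fixed seeds", {
  cfg <- scene_config(duration_s = 5, density = "dense", seed = 8)
  expect_identical(gen_scene(cfg)$samples, gen_scene(cfg)$samples)
  sc <- gen_scene(cfg)
  sm <- subject_model(seed = 9)
  expect_identical(gen_salience(sc, sm)$percent, gen_salience(sc, sm)$percent)
  mix <- eeg_mix_config(seed = 10)
  d <- rnorm(200)
  expect_identical(gen_band_energy(d, mix)$energy, gen_band_energy(d, mix)$energy)
})

test_that("raw EEG generator plants energy in the requested band", {
  sig <- gen_raw_eeg(20, rate = 256, n_channels = 2,
                     band_amplitudes = c(Alpha = 3), seed = 1)
  expect_equal(dim(sig), c(2L, 20 * 256))
  be <- band_energy(sig, rate = 256)
  raw <- attr(be, "raw_power")
  mean_by_band <- tapply(raw, be$band, mean)
  expect_equal(names(which.max(mean_by_band)), "Alpha")
})
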