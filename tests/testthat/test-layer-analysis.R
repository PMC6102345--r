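# Layer trends, cumulative variance, random baseline, group contrasts.

make_profile <- function(values_by_layer, reps = 1) {
  tibble::tibble(layer = rep(ANALYZED_LAYERS, each = reps),
                 value = as.numeric(t(replicate(reps, values_by_layer))))
}

test_that("an exactly linear profile is fit exactly", {
  prof <- make_profile(0.1 + 0.5 * (0:5))
  tr <- layer_trend(prof)
  expect_equal(tr$slope, 0.5, tolerance = 1e-12)
  expect_equal(sum(residuals(tr$fit)^2), 0, tolerance = 1e-20)
  expect_true(tr$conf.low <= tr$slope && tr$slope <= tr$conf.high)
})

test_that("a constant profile has zero slope and p near 1", {
  tr <- layer_trend(make_profile(rep(0.3, 6), reps = 4))
  expect_equal(tr$slope, 0, tolerance = 1e-12)
  expect_gte(tr$p.value, 0.99)
})

test_that("tidy and glance return the regression summary", {
  prof <- make_profile(0.6 - 0.05 * (0:5), reps = 10)
  prof$value <- prof$value + rnorm(nrow(prof), sd = 0.01)
  tr <- layer_trend(prof)
  td <- tidy(tr)
  expect_equal(td$term, c("(Intercept)", "layer_index"))
  gl <- glance(tr)
  expect_equal(gl$slope, tr$slope)
  expect_equal(gl$df, nrow(prof) - 2)
  expect_s3_class(autoplot(tr), "ggplot")
})

test_that("the 99% CI covers a simulated slope at its nominal rate", {
  true_slope <- 0.03
  covered <- vapply(1:100, function(run) {
    set.seed(run)
    prof <- tibble::tibble(
      layer = rep(ANALYZED_LAYERS, each = 200),
      value = 0.2 + true_slope * rep(0:5, each = 200) + rnorm(1200, sd = 0.05))
    tr <- layer_trend(prof)
    tr$conf.low <= true_slope && true_slope <= tr$conf.high
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("a perfect first-layer predictor saturates cumulative variance", {
  set.seed(13)
  target <- rnorm(500)
  layers <- list(L1 = target, L2 = rnorm(500), L3 = rnorm(500))
  cv <- cumulative_variance(target, layers)
  expect_equal(cv$cumulative, rep(1, 3), tolerance = 1e-10)
})

test_that("orthogonal equal-variance components split the variance 0.5 / 1.0", {
  n <- 1000
  t <- seq_len(n)
  s1 <- sqrt(2) * sin(2 * pi * 5 * t / n)
  s2 <- sqrt(2) * cos(2 * pi * 9 * t / n)
  target <- s1 + s2
  cv <- cumulative_variance(target, list(a = s1, b = s2,
                                         c = sqrt(2) * sin(2 * pi * 13 * t / n)))
  expect_equal(cv$cumulative[1], 0.5, tolerance = 0.05)
  expect_equal(cv$cumulative[2], 1.0, tolerance = 0.05)
  expect_equal(cv$cumulative[3], 1.0, tolerance = 0.05)
})

test_that("orthogonal random layers explain almost nothing", {
  set.seed(14)
  target <- rnorm(1000)
  layers <- replicate(6, rnorm(1000), simplify = FALSE)
  cv <- cumulative_variance(target, layers)
  expect_true(all(cv$cumulative < 0.03))
})

test_that("cumulative variance is monotone, bounded and rejects degenerate targets", {
  for (run in 1:20) {
    set.seed(run)
    target <- rnorm(300)
    layers <- replicate(6, rnorm(300) + 0.3 * target * runif(1), simplify = FALSE)
    cv <- cumulative_variance(target, layers)
    expect_true(all(diff(cv$cumulative) >= -1e-12))
    expect_true(all(cv$cumulative <= 1 + 1e-12))
  }
  expect_error(cumulative_variance(rep(1, 100), list(rnorm(100))), "zero variance")
  expect_error(cumulative_variance(rnorm(100), list(rnorm(50))), "length")
})

test_that("the random baseline shares the first step and is seeded", {
  set.seed(15)
  target <- rnorm(800)
  layers <- replicate(6, rnorm(800) + 0.2 * target, simplify = FALSE)
  names(layers) <- ANALYZED_LAYERS
  cv <- cumulative_variance(target, layers)
  rb1 <- random_baseline(target, layers, seed = 5)
  rb2 <- random_baseline(target, layers, seed = 5)
  expect_identical(rb1, rb2)
  expect_equal(rb1$cumulative[1], cv$cumulative[1], tolerance = 1e-12)
  expect_false(identical(rb1, random_baseline(target, layers, seed = 6)))
})

test_that("chance increments of the random baseline match the analytic expectation", {
  # regressing an independent N(0,1) regressor on an n-sample target
  # removes an expected fraction 1/(n-1) of the residual variance
  n <- 1000
  run_means <- vapply(1:100, function(run) {
    set.seed(600000 + run)
    target <- rnorm(n)
    layers <- c(list(first = rnorm(n) + 0.3 * target),
                replicate(5, rnorm(n), simplify = FALSE))
    rb <- random_baseline(target, layers, seed = 800000 + run)
    resid_frac <- 1 - rb$cumulative            # residual variance fraction
    mean((resid_frac[-6] - resid_frac[-1]) / resid_frac[-6])
  }, numeric(1))
  expected <- 1 / (n - 1)
  se <- sd(run_means) / sqrt(length(run_means))
  expect_lt(abs(mean(run_means) - expected), 2 * se + 1e-6)
})

test_that("group contrasts detect a planted early-layer advantage", {
  set.seed(17)
  # dense minus sparse: planted deficit in the three early layers
  sparse <- make_profile(c(0.6, 0.6, 0.6, 0.3, 0.3, 0.3), reps = 8)
  sparse$value <- sparse$value + rnorm(nrow(sparse), sd = 0.03)
  dense <- make_profile(c(0.35, 0.35, 0.35, 0.3, 0.3, 0.3), reps = 8)
  dense$value <- dense$value + rnorm(nrow(dense), sd = 0.03)
  ct <- compare_groups(dense, sparse)
  early <- ct$differences$difference[1:3]
  expect_true(all(early < 0))
  expect_lt(ct$p.value, 0.05)
  expect_equal(ct$df, 4)
  # antisymmetry
  ct_swap <- compare_groups(sparse, dense)
  expect_equal(ct_swap$differences$difference, -ct$differences$difference)
})

test_that("identical groups give zero differences and p near 1", {
  prof <- make_profile(c(0.5, 0.45, 0.4, 0.35, 0.3, 0.25), reps = 3)
  ct <- compare_groups(prof, prof)
  expect_true(all(ct$differences$difference == 0))
  expect_gte(ct$p.value, 0.99)
  bad <- prof[prof$layer != "Embed", ]
  expect_error(compare_groups(prof, bad), "match")
})

test_that("per-category cumulative variance runs on event-window stacks", {
  set.seed(18)
  target <- rnorm(400)
  layers <- replicate(6, rnorm(400) + 0.3 * target, simplify = FALSE)
  names(layers) <- ANALYZED_LAYERS
  cats <- sample(c("speech", "music"), 400, replace = TRUE)
  for (cat in c("speech", "music")) {
    keep <- cats == cat
    cv <- cumulative_variance(target[keep], lapply(layers, `[`, keep))
    expect_true(all(diff(cv$cumulative) >= -1e-12))
    expect_gt(cv$cumulative[6], 0)
  }
})
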