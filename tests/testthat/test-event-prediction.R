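# Feature slopes, bin tables, and cross-validated LDA with ROC.

test_that("the slope of a linear ramp is its rate of change", {
  x <- 2 * (0:99) / 10                    # 2 units per second at 10 Hz
  s <- feature_slope(x, rate = 10)
  expect_equal(as.numeric(s[5:95]), rep(2, 91), tolerance = 1e-10)
  expect_true(all(feature_slope(rep(3, 50), rate = 10) == 0))
  expect_error(feature_slope(c(1, 2), rate = 10), "3 samples")
})

test_that("feature slope equals a brute-force convolution oracle", {
  set.seed(19)
  x <- rnorm(80)
  got <- as.numeric(feature_slope(x, rate = 10, ma_window = 5, ma_passes = 3))
  # oracle: explicit first difference then three explicit edge-truncated
  # moving-average loops
  d <- c(diff(x)[1], diff(x)) * 10
  for (pass in 1:3) {
    sm <- numeric(length(d))
    for (i in seq_along(d)) {
      sm[i] <- mean(d[max(1, i - 2):min(length(d), i + 2)])
    }
    d <- sm
  }
  expect_equal(got, d, tolerance = 1e-12)
})

test_that("bin counts and labels follow the framing arithmetic", {
  feats <- tibble::tibble(time = (0:1179) / 10, f = rnorm(1180))
  tab <- build_bins(feats, events = numeric(), rate = 10)
  expect_equal(nrow(tab), 233L)           # floor((118 - 2)/0.5) + 1
  expect_true(all(tab$label == 0L))
  tab2 <- build_bins(feats, events = c(10.0), rate = 10)
  covered <- tab2$bin_start <= 10.0 & 10.0 < tab2$bin_start + 2
  expect_identical(tab2$label == 1L, covered)
  expect_warning(build_bins(feats, events = c(10, 500), rate = 10), "skipped")
})

test_that("bin features are per-bin means of the underlying track", {
  feats <- tibble::tibble(time = (0:199) / 10, f = rnorm(200))
  tab <- build_bins(feats, events = numeric(), rate = 10)
  k <- 7
  idx <- which(feats$time >= tab$bin_start[k] & feats$time < tab$bin_start[k] + 2)
  expect_equal(tab$f[k], mean(feats$f[idx]), tolerance = 1e-12)
})

test_that("alignment shifts a lagged feature back onto the target", {
  set.seed(20)
  base <- as.numeric(conditioned_noise())
  lagged <- c(rep(base[1], 8), head(base, -8))   # feature delayed 0.8 s
  feats <- tibble::tibble(time = (seq_along(base) - 1) / 10, f = lagged)
  tab_aligned <- build_bins(feats, events = numeric(), rate = 10, align_to = base)
  tab_raw <- build_bins(feats, events = numeric(), rate = 10)
  base_bins <- build_bins(tibble::tibble(time = feats$time, f = base),
                          events = numeric(), rate = 10)
  r_aligned <- cor(tab_aligned$f, base_bins$f)
  r_raw <- cor(tab_raw$f, base_bins$f)
  expect_gt(r_aligned, r_raw)
  expect_gt(r_aligned, 0.95)
})

test_that("well-separated classes give near-perfect AUC", {
  set.seed(21)
  tab <- tibble::tibble(x = c(rnorm(100), rnorm(100, 10)),
                        y = rnorm(200),
                        label = rep(0:1, each = 100))
  res <- lda_classify(tab, folds = 5, seed = 1)
  expect_gte(res$auc, 0.99)
})

test_that("permuted labels give chance-level AUC on average", {
  set.seed(22)
  tab <- tibble::tibble(x = rnorm(200), y = rnorm(200),
                        label = rep(0:1, each = 100))
  aucs <- vapply(1:50, function(i) {
    perm <- tab
    perm$label <- sample(tab$label)
    lda_classify(perm, folds = 5, seed = i)$auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.55)
})

test_that("LDA scores agree with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(23)
  X <- rbind(matrix(rnorm(60 * 3), 60, 3),
             matrix(rnorm(60 * 3, mean = 1), 60, 3))
  y <- rep(0:1, each = 60)
  w <- audsal:::lda_direction(X, y)
  ref <- MASS::lda(X, grouping = y)
  proj_ref <- X %*% ref$scaling[, 1]
  proj_got <- X %*% w
  expect_gt(abs(cor(proj_ref, proj_got)), 1 - 1e-10)
})

test_that("AUC agrees with the pROC reference and ROC is monotone", {
  skip_if_not_installed("pROC")
  set.seed(24)
  scores <- rnorm(150)
  labels <- rbinom(150, 1, plogis(scores))
  got <- audsal:::roc_from_scores(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(got$auc, as.numeric(ref), tolerance = 1e-10)
  expect_true(all(diff(got$curve$fpr) >= 0))
  expect_true(all(diff(got$curve$tpr) >= 0))
})

test_that("the ROC is invariant to strictly monotone score transforms", {
  set.seed(25)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.4)
  a <- audsal:::roc_from_scores(scores, labels)
  b <- audsal:::roc_from_scores(exp(scores) + 3, labels)
  expect_equal(a$curve$fpr, b$curve$fpr)
  expect_equal(a$curve$tpr, b$curve$tpr)
  expect_equal(a$auc, b$auc)
})

test_that("fold assignment is stratified within one bin of the global ratio", {
  set.seed(26)
  y <- rbinom(237, 1, 0.3)
  folds <- audsal:::stratified_folds(y, 5, seed = 2)
  for (cls in 0:1) {
    counts <- base::table(folds[y == cls])
    expect_lte(max(counts) - min(counts), 1)
  }
  # seeded determinism
  expect_identical(folds, audsal:::stratified_folds(y, 5, seed = 2))
})

test_that("a singular covariance triggers ridge regularization with a warning", {
  set.seed(27)
  x <- rnorm(100)
  tab <- tibble::tibble(a = x, b = x, label = rep(0:1, 50))  # collinear
  w <- capture_warnings(res <- lda_classify(tab, folds = 5, seed = 3))
  expect_true(any(grepl("ridge", w)))
  expect_true(is.finite(res$auc))
})

test_that("glance and autoplot summarize a roc_result", {
  set.seed(28)
  tab <- tibble::tibble(x = c(rnorm(40), rnorm(40, 2)), label = rep(0:1, each = 40))
  res <- lda_classify(tab, folds = 4, seed = 1)
  gl <- glance(res)
  expect_equal(gl$n_bins, 80L)
  expect_equal(gl$n_folds, 4L)
  expect_s3_class(autoplot(res), "ggplot")
})
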