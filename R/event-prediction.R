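# Salient-event prediction: feature slopes, overlapping time bins, and
# cross-validated linear discriminant analysis with ROC summary.

#' Slope of a feature track
#'
#' The slope is the first difference of the signal (scaled to units per
#' second) smoothed with three iterations of an equally weighted centered
#' moving average.  The output has the same length as the input (the
#' first sample repeats the first difference).
#'
#' @param x Numeric track, or tibble whose first non-`time` numeric column
#'   is used.
#' @param rate Sampling rate in Hz (default 10, or the `"rate"` attribute).
#' @param ma_window Moving-average window in samples (default 5).
#' @param ma_passes Number of smoothing passes (default 3).
#' @return Numeric slope series, same length as `x`, attribute `"rate"`.
#' @export
feature_slope <- function(x, rate = NULL, ma_window = 5L, ma_passes = 3L) {
  if (is.data.frame(x)) {
    if (is.null(rate)) rate <- attr(x, "rate")
    col <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], "time")[1]
    x <- x[[col]]
  }
  if (is.null(rate)) rate <- attr(x, "rate")
  if (is.null(rate)) rate <- 10
  x <- as.numeric(x)
  if (length(x) < 3L) stop("track must have at least 3 samples", call. = FALSE)
  d <- diff(x) * rate
  d <- c(d[1L], d)
  for (i in seq_len(ma_passes)) d <- moving_average(d, ma_window)
  attr(d, "rate") <- rate
  d
}

#' Build the overlapping-bin table for event prediction
#'
#' Divides the common time base into overlapping bins (default 2 s long,
#' advanced by 0.5 s), averages every feature column within each bin, and
#' labels a bin 1 exactly when a salient-event onset falls inside it.
#' When `align_to` is given, each feature column is first shifted by the
#' lag (within `max_lag_s`) that maximizes its correlation with the
#' alignment series, mirroring the time alignment used in the
#' correlation analyses.
#'
#' @param features Tibble with a `time` column and one numeric column per
#'   predictor (feature slopes and/or layer surprisal), sampled uniformly.
#' @param events Event tibble with `time_s`, or numeric vector of onsets.
#' @param rate Sampling rate in Hz (default 10, or the `"rate"` attribute).
#' @param bin_s Bin length in seconds (default 2).
#' @param step_s Bin step in seconds (default 0.5).
#' @param align_to Optional numeric series (same rate, same span) to which
#'   every feature column is lag-aligned before binning.
#' @param max_lag_s Alignment search range in seconds (default 3).
#' @return A tibble with `bin_start`, one column per feature, and `label`
#'   (0/1); events outside the series span are counted in attribute
#'   `"skipped_events"`.
#' @export
build_bins <- function(features, events, rate = NULL, bin_s = 2, step_s = 0.5,
                       align_to = NULL, max_lag_s = 3) {
  features <- tibble::as_tibble(features)
  if (is.null(rate)) rate <- attr(features, "rate")
  if (is.null(rate)) rate <- 10
  if (!"time" %in% names(features)) {
    features$time <- (seq_len(nrow(features)) - 1L) / rate
  }
  cols <- setdiff(names(features), "time")
  n <- nrow(features)
  dur <- n / rate
  if (dur < bin_s) stop("series shorter than one bin", call. = FALSE)
  if (!is.null(align_to)) {
    for (cl in cols) {
      # positive lag: the alignment target follows this feature, so the
      # feature is delayed by that amount to meet it
      lag <- max_lagged_correlation(features[[cl]], as.numeric(align_to),
                                    rate = rate, max_lag_s = max_lag_s)$lag_s
      features[[cl]] <- shift_series(features[[cl]], round(lag * rate))
    }
  }
  t0 <- features$time[1L]
  n_bins <- floor((dur - bin_s) / step_s) + 1L
  starts <- t0 + (seq_len(n_bins) - 1L) * step_s
  ev_times <- if (is.data.frame(events)) events$time_s else as.numeric(events)
  skipped <- sum(ev_times < t0 | ev_times >= t0 + dur)
  if (skipped > 0) {
    warning(skipped, " event(s) outside the series span were skipped")
  }
  # per-bin means via index arithmetic on the uniform grid
  rel <- features$time - t0
  out <- tibble::tibble(bin_start = starts)
  for (cl in cols) {
    out[[cl]] <- vapply(starts, function(s) {
      idx <- which(rel >= s - t0 & rel < s - t0 + bin_s)
      mean(features[[cl]][idx])
    }, numeric(1))
  }
  out$label <- vapply(starts, function(s) {
    as.integer(any(ev_times >= s & ev_times < s + bin_s))
  }, integer(1))
  attr(out, "skipped_events") <- skipped
  attr(out, "rate") <- rate
  out
}

#' Cross-validated LDA prediction of salient-event bins
#'
#' Fits a two-class linear discriminant (class-conditional Gaussians with
#' pooled covariance) on the training folds, scores the held-out bins by
#' the discriminant projection, pools the held-out scores across the
#' (seeded, stratified) folds, and sweeps a threshold over the pooled
#' scores to trace a ROC curve.  A singular pooled covariance is
#' ridge-regularized (epsilon `1e-6` times the mean diagonal) with a
#' warning.
#'
#' @param table A bin table from [build_bins()] (columns: optional
#'   `bin_start`, predictors, `label`).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param features Optional character vector restricting the predictor
#'   columns.
#' @return An object of class `roc_result`: list with `curve` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `scores`, `labels`, `folds`.
#' @examples
#' set.seed(1)
#' tab <- tibble::tibble(x = c(rnorm(50), rnorm(50, 3)),
#'                       label = rep(0:1, each = 50))
#' lda_classify(tab, folds = 5, seed = 1)$auc
#' @export
lda_classify <- function(table, folds = 5L, seed = 1L, features = NULL) {
  table <- tibble::as_tibble(table)
  if (!"label" %in% names(table)) stop("`table` needs a `label` column", call. = FALSE)
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        c("label", "bin_start"))
  }
  X <- as.matrix(table[, features, drop = FALSE])
  y <- table$label
  if (!is_binary(y)) stop("labels must be 0/1", call. = FALSE)
  fold_id <- stratified_folds(y, folds, seed)
  counts <- base::table(fold_id, y)
  if (any(counts == 0L)) {
    stop("both classes must be present in every training fold", call. = FALSE)
  }
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    train <- fold_id != f
    w <- lda_direction(X[train, , drop = FALSE], y[train])
    scores[!train] <- X[!train, , drop = FALSE] %*% w
  }
  roc <- roc_from_scores(scores, y)
  structure(
    list(curve = roc$curve, auc = roc$auc, scores = scores, labels = y,
         folds = fold_id, features = features),
    class = "roc_result"
  )
}

# Seeded stratified fold assignment: within each class, shuffled
# round-robin, so per-fold class counts differ by at most one.
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    id <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
}

# Fisher discriminant direction with pooled within-class covariance.
lda_direction <- function(X, y, ridge_eps = 1e-6) {
  X0 <- X[y == 0, , drop = FALSE]
  X1 <- X[y == 1, , drop = FALSE]
  mu0 <- colMeans(X0)
  mu1 <- colMeans(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  S <- ((n0 - 1) * cov_or_zero(X0) + (n1 - 1) * cov_or_zero(X1)) / (n0 + n1 - 2)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    warning("singular pooled covariance; applying ridge regularization")
    eps <- ridge_eps * mean(diag(S))
    if (!is.finite(eps) || eps <= 0) eps <- ridge_eps
    w <- solve(S + diag(eps, ncol(S)), mu1 - mu0)
  }
  w
}

cov_or_zero <- function(X) {
  if (nrow(X) < 2L) return(matrix(0, ncol(X), ncol(X)))
  stats::cov(X)
}

# ROC curve and AUC from scores (higher score = more event-like).
# AUC is the Mann-Whitney probability with ties counted one half.
roc_from_scores <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct threshold
  curve <- tibble::tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, fp[keep] / n0),
    tpr = c(0, tp[keep] / n1)
  )
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(curve = curve, auc = auc)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d bins, %d positive)\n",
              x$auc, length(x$labels), sum(x$labels == 1)))
  invisible(x)
}

#' @rdname lda_classify
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname lda_classify
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_bins = length(x$labels),
                 n_positive = sum(x$labels == 1),
                 n_folds = length(unique(x$folds)))
}
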