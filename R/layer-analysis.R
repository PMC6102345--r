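# Layerwise statistics: trend of a metric across network depth, cumulative
# variance explained by sequential residual regression, its random
# baseline, and early-vs-deep group contrasts.

layer_index <- function(layer) {
  idx <- match(layer, ANALYZED_LAYERS)
  if (any(is.na(idx))) {
    stop("unknown layer name(s): ",
         paste(unique(layer[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx - 1L
}

#' Linear trend of a metric across network layers
#'
#' Fits an ordinary least squares regression of the metric on the layer
#' index (0 for Pool2 through 5 for Embed), pooling all replicates, and
#' tests the slope with a t test.  Reports the slope per layer step, its t
#' statistic, residual degrees of freedom, p value and 99% confidence
#' interval.
#'
#' @param profile A tibble with columns `layer` (one of the six analyzed
#'   layer names) and `value`; multiple rows per layer are replicates
#'   (scenes, events, bands, ...).
#' @return An object of class `layer_trend` supporting [tidy()],
#'   [glance()], [autoplot()][ggplot2::autoplot] and `print()`.
#' @examples
#' prof <- tibble::tibble(layer = rep(ANALYZED_LAYERS, each = 3),
#'                        value = rep(6:1, each = 3) / 10 + rnorm(18, sd = 0.01))
#' glance(layer_trend(prof))
#' @export
layer_trend <- function(profile) {
  profile <- tibble::as_tibble(profile)
  if (!all(c("layer", "value") %in% names(profile))) {
    stop("`profile` needs columns `layer` and `value`", call. = FALSE)
  }
  if (length(unique(profile$layer)) < 2L || nrow(profile) < 3L) {
    stop("need at least 2 layers and 3 values", call. = FALSE)
  }
  df <- tibble::tibble(index = layer_index(profile$layer), value = profile$value)
  fit <- lm(value ~ index, data = df)
  sm <- suppressWarnings(summary(fit))
  slope <- coef(fit)[["index"]]
  se <- sm$coefficients["index", "Std. Error"]
  t_stat <- sm$coefficients["index", "t value"]
  dof <- fit$df.residual
  p <- sm$coefficients["index", "Pr(>|t|)"]
  ci <- suppressWarnings(confint(fit, "index", level = 0.99))
  exact_fit <- !is.finite(se) || se == 0 || !is.finite(t_stat) ||
    sm$sigma < 1e-10 * (sd(df$value) + 1e-300) || sm$sigma < 1e-12
  if (exact_fit) {
    # residual variance is numerically zero: the fit is exact
    scale <- max(abs(df$value), 1)
    t_stat <- if (abs(slope) < 1e-12 * scale) 0 else sign(slope) * Inf
    p <- if (t_stat == 0) 1 else 0
    ci <- c(slope, slope)
  }
  structure(
    list(slope = slope, se = se, statistic = t_stat, df = dof, p.value = p,
         conf.low = ci[1], conf.high = ci[2], fit = fit, profile = profile),
    class = "layer_trend"
  )
}

#' @export
print.layer_trend <- function(x, ...) {
  cat(sprintf("Layer trend: slope = %.4g per layer step, t(%d) = %.3g, p = %.3g\n",
              x$slope, x$df, x$statistic, x$p.value))
  cat(sprintf("  99%% CI [%.4g, %.4g]\n", x$conf.low, x$conf.high))
  invisible(x)
}

#' @rdname layer_trend
#' @param x A `layer_trend` object.
#' @param ... Unused.
#' @export
tidy.layer_trend <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "layer_index"),
    estimate = coef(x$fit),
    std.error = summary(x$fit)$coefficients[, "Std. Error"],
    statistic = summary(x$fit)$coefficients[, "t value"],
    p.value = summary(x$fit)$coefficients[, "Pr(>|t|)"]
  )
}

#' @rdname layer_trend
#' @export
glance.layer_trend <- function(x, ...) {
  tibble::tibble(slope = x$slope, statistic = x$statistic, df = x$df,
                 p.value = x$p.value, conf.low = x$conf.low,
                 conf.high = x$conf.high)
}

#' Cumulative variance of a target explained by successive layers
#'
#' Performs consecutive simple linear regressions, lower layers first:
#' the target (e.g. the conditioned salience curve, or a concatenation of
#' event windows) is regressed on the first layer's surprisal; the
#' cumulative variance explained after layer k is one minus the residual
#' variance divided by the variance of the original target; the residual
#' then becomes the target for the next layer's regression.  The sequence
#' is non-decreasing and bounded by 1.
#'
#' @param target Numeric series (common time base with the layer series).
#' @param surprisal_by_layer Named list (or column matrix) of per-layer
#'   surprisal series in shallow-to-deep order, each the same length as
#'   `target`.
#' @return A tibble with columns `layer` and `cumulative`.
#' @export
cumulative_variance <- function(target, surprisal_by_layer) {
  target <- as.numeric(target)
  if (var(target) == 0) stop("target has zero variance", call. = FALSE)
  if (is.matrix(surprisal_by_layer)) {
    surprisal_by_layer <- as.list(as.data.frame(surprisal_by_layer))
  }
  layers <- names(surprisal_by_layer)
  if (is.null(layers)) layers <- paste0("layer", seq_along(surprisal_by_layer))
  var0 <- var(target)
  resid <- target
  cum <- numeric(length(surprisal_by_layer))
  for (k in seq_along(surprisal_by_layer)) {
    s <- as.numeric(surprisal_by_layer[[k]])
    if (length(s) != length(target)) {
      stop("layer series ", layers[k], " length does not match the target",
           call. = FALSE)
    }
    fit <- lm(resid ~ s)
    resid <- residuals(fit)
    cum[k] <- 1 - var(resid) / var0
  }
  tibble::tibble(layer = layers, cumulative = cum)
}

#' Random baseline for the cumulative-variance analysis
#'
#' Repeats [cumulative_variance()] with all layers after the first
#' `keep_first` replaced by series drawn from a standard normal
#' distribution (mean 0, variance 1), giving the chance level of
#' improvement from simply adding regressors.
#'
#' @inheritParams cumulative_variance
#' @param keep_first Number of leading layers kept intact (default 1).
#' @param seed Integer seed for the replacement series.
#' @return A tibble with columns `layer` and `cumulative`.
#' @export
random_baseline <- function(target, surprisal_by_layer, keep_first = 1L,
                            seed = 1L) {
  if (is.matrix(surprisal_by_layer)) {
    surprisal_by_layer <- as.list(as.data.frame(surprisal_by_layer))
  }
  n <- length(as.numeric(target))
  with_seed(seed, {
    replaced <- surprisal_by_layer
    if (length(replaced) > keep_first) {
      for (k in (keep_first + 1L):length(replaced)) {
        replaced[[k]] <- rnorm(n)
      }
    }
    cumulative_variance(target, replaced)
  })
}

#' Contrast two layer profiles (e.g. dense vs sparse scenes)
#'
#' Computes the per-layer difference in mean metric between conditions a
#' and b, and tests whether the difference differs between early layers
#' (Pool2, Pool3, Conv4) and deep layers (Pool4, FC1, Embed) with a
#' two-sample pooled-variance t test on the per-layer differences
#' (3 early vs 3 deep values, 4 degrees of freedom).
#'
#' @param profile_a,profile_b Tibbles with columns `layer` and `value`
#'   over the same six layers (replicates allowed).
#' @return A list of class `layer_contrast` with `differences` (tibble
#'   `layer`, `difference`), `statistic`, `df`, `p.value`.
#' @export
compare_groups <- function(profile_a, profile_b) {
  mean_by_layer <- function(p) {
    tibble::as_tibble(p) |>
      dplyr::group_by(.data$layer) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  a <- mean_by_layer(profile_a)
  b <- mean_by_layer(profile_b)
  if (!setequal(a$layer, b$layer)) stop("layer sets do not match", call. = FALSE)
  merged <- dplyr::inner_join(a, b, by = "layer", suffix = c("_a", "_b")) |>
    dplyr::mutate(difference = .data$value_a - .data$value_b,
                  index = layer_index(.data$layer)) |>
    dplyr::arrange(.data$index)
  early <- merged$difference[merged$index <= 2L]
  deep <- merged$difference[merged$index >= 3L]
  tt <- tryCatch(t.test(early, deep, var.equal = TRUE), error = function(e) NULL)
  if (!is.null(tt) && !is.finite(tt$statistic)) tt <- NULL
  if (is.null(tt)) {
    # essentially constant data: no early-vs-deep difference to detect
    tt <- list(statistic = 0, parameter = length(early) + length(deep) - 2,
               p.value = 1)
  }
  structure(
    list(differences = merged[, c("layer", "difference")],
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value),
    class = "layer_contrast"
  )
}

#' @export
print.layer_contrast <- function(x, ...) {
  cat("Early vs deep layer contrast of condition differences:\n")
  print(x$differences)
  cat(sprintf("  t(%g) = %.3g, p = %.3g\n", x$df, x$statistic, x$p.value))
  invisible(x)
}
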