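#' Network surprisal: distance of current layer activity from its history
#'
#' For each frame, surprisal is the Euclidean distance between the layer's
#' activation vector at that frame and the element-wise mean of its
#' activation vectors over the strictly preceding `history_window_s`
#' seconds (default 4 s).  A constant activation pattern therefore yields
#' zero surprisal, while a change in the pattern over seconds yields a
#' large value.  Frames with less than `min_history_s` of history are
#' undefined (`NA`); frames with at least `min_history_s` but less than
#' the full window use the history that is available.
#'
#' @param acts A `layer_activations` object from [activation_timeseries()],
#'   or a single frames-by-units numeric matrix.
#' @param history_window_s History window length in seconds (default 4).
#' @param min_history_s Minimum history required for a defined value
#'   (default 1).
#' @param frame_rate Frames per second when `acts` is a bare matrix.
#' @return A tibble with columns `layer`, `time`, `surprisal` (NA where
#'   undefined), with attributes `"rate"`, `"history_window_s"` and
#'   `"min_history_s"`.
#' @examples
#' a <- matrix(rnorm(15), nrow = 5)  # 5 frames, 3 units
#' compute_surprisal(a, history_window_s = 0.4, min_history_s = 0.1,
#'                   frame_rate = 10)
#' @export
compute_surprisal <- function(acts, history_window_s = 4, min_history_s = 1,
                              frame_rate = NULL) {
  if (inherits(acts, "layer_activations")) {
    out <- purrr::imap(acts$layers, function(m, nm) {
      tibble::tibble(
        layer = nm, time = acts$time,
        surprisal = surprisal_vector(m, acts$frame_rate, history_window_s,
                                     min_history_s))
    })
    res <- dplyr::bind_rows(out)
    rate <- acts$frame_rate
  } else {
    if (is.null(frame_rate)) stop("`frame_rate` must be given for a bare matrix",
                                  call. = FALSE)
    m <- as.matrix(acts)
    res <- tibble::tibble(
      layer = "layer", time = (seq_len(nrow(m)) - 1L) / frame_rate,
      surprisal = surprisal_vector(m, frame_rate, history_window_s, min_history_s))
    rate <- frame_rate
  }
  attr(res, "rate") <- rate
  attr(res, "history_window_s") <- history_window_s
  attr(res, "min_history_s") <- min_history_s
  res
}

surprisal_vector <- function(m, frame_rate, history_window_s, min_history_s) {
  n <- nrow(m)
  if (n == 0L) stop("empty activation series", call. = FALSE)
  hw <- max(1L, round(history_window_s * frame_rate))
  mh <- max(1L, round(min_history_s * frame_rate))
  if (n <= mh) stop("activation series shorter than the minimum history",
                    call. = FALSE)
  # cumulative sums over frames allow O(1) history means per frame
  cs <- rbind(0, apply(m, 2L, cumsum))
  vals <- rep(NA_real_, n)
  t_idx <- (mh + 1L):n
  k <- pmin(hw, t_idx - 1L)                  # frames of available history
  hist_mean <- (cs[t_idx, , drop = FALSE] - cs[t_idx - k, , drop = FALSE]) / k
  d <- m[t_idx, , drop = FALSE] - hist_mean
  vals[t_idx] <- sqrt(rowSums(d * d))
  vals
}
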