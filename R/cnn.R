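# VGG-style audio classification network.
#
# The network alternates 3x3 same-padded convolutions (each followed by a
# rectified linear unit) with non-overlapping 2x2 max pooling, then two
# fully connected layers (4096 and 128 units, both rectified) and a linear
# 4923-way prediction layer.  For a 96 x 64 input spectrogram the layer
# dimensions are:
#
#   Conv1 96x64x64   Pool1 48x32x64
#   Conv2 48x32x128  Pool2 24x16x128  (49,152 outputs)
#   Conv3 24x16x256  Pool3 12x8x256   (24,576 outputs)
#   Conv4 12x8x512   (49,152)         Pool4 6x4x512 (12,288)
#   FC1 4096         Embed 128        Predic 4923
#
# Only Pool2, Pool3, Conv4, Pool4, FC1 and Embed are carried into the
# analyses.  The pipeline is weight-agnostic: seeded random weights are
# the default, and trained weights can be dropped in from a file.

CNN_INPUT_FRAMES <- 96L
CNN_INPUT_BANDS <- 64L

cnn_layer_plan <- function() {
  list(
    list(name = "Conv1", type = "conv", c_in = 1L,   c_out = 64L,  h = 96L, w = 64L),
    list(name = "Pool1", type = "pool", h = 48L, w = 32L, c = 64L),
    list(name = "Conv2", type = "conv", c_in = 64L,  c_out = 128L, h = 48L, w = 32L),
    list(name = "Pool2", type = "pool", h = 24L, w = 16L, c = 128L),
    list(name = "Conv3", type = "conv", c_in = 128L, c_out = 256L, h = 24L, w = 16L),
    list(name = "Pool3", type = "pool", h = 12L, w = 8L, c = 256L),
    list(name = "Conv4", type = "conv", c_in = 256L, c_out = 512L, h = 12L, w = 8L),
    list(name = "Pool4", type = "pool", h = 6L, w = 4L, c = 512L),
    list(name = "FC1",   type = "fc",  d_in = 12288L, d_out = 4096L),
    list(name = "Embed", type = "fc",  d_in = 4096L,  d_out = 128L),
    list(name = "Predic", type = "fc", d_in = 128L,   d_out = 4923L)
  )
}

#' Expected flattened output widths of the network layers
#'
#' @return Named integer vector of "total number of outputs" per layer,
#'   including the 96 x 64 input.
#' @export
cnn_layer_widths <- function() {
  c(Input = 6144L, Conv1 = 393216L, Pool1 = 98304L, Conv2 = 196608L,
    Pool2 = 49152L, Conv3 = 98304L, Pool3 = 24576L, Conv4 = 49152L,
    Pool4 = 12288L, FC1 = 4096L, Embed = 128L, Predic = 4923L)
}

#' Configuration for the audio CNN
#'
#' @param weight_source `"seeded_random"` (default) for reproducible He-scaled
#'   Gaussian weights with zero biases, or `"file"` to load weights.
#' @param weight_file Path to an `.rds` file holding a named list with, per
#'   layer, `W` (matrix in the layer's im2col/input-by-output shape) and `b`
#'   (bias vector); shapes are validated against the architecture.
#' @param seed Integer seed for `"seeded_random"` weights.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(weight_source = c("seeded_random", "file"),
                       weight_file = NULL, seed = 1L) {
  weight_source <- match.arg(weight_source)
  if (weight_source == "file" && is.null(weight_file)) {
    stop("`weight_file` is required when weight_source = \"file\"", call. = FALSE)
  }
  structure(list(weight_source = weight_source, weight_file = weight_file,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Instantiate the audio CNN
#'
#' Builds the network with either seeded random weights (He-scaled
#' Gaussians, zero biases; reproducible under a fixed seed) or weights
#' loaded from a file.  A forward pass on a 96 x 64 input reproduces the
#' documented layer dimensions exactly.
#'
#' @param config A [cnn_config()] (default: seeded random weights, seed 1).
#' @return An object of class `audio_cnn`.
#' @examples
#' net <- build_network(cnn_config(seed = 1))
#' acts <- forward_layers(net, matrix(0, 96, 64))
#' vapply(acts, length, integer(1))
#' @export
build_network <- function(config = cnn_config()) {
  if (!inherits(config, "cnn_config")) stop("`config` must be a cnn_config")
  plan <- cnn_layer_plan()
  weights <- if (config$weight_source == "seeded_random") {
    with_seed(config$seed, {
      out <- list()
      for (layer in plan) {
        if (layer$type == "conv") {
          fan_in <- 9L * layer$c_in
          out[[layer$name]] <- list(
            W = matrix(rnorm(fan_in * layer$c_out, sd = sqrt(2 / fan_in)),
                       fan_in, layer$c_out),
            b = numeric(layer$c_out))
        } else if (layer$type == "fc") {
          out[[layer$name]] <- list(
            W = matrix(rnorm(layer$d_in * layer$d_out, sd = sqrt(2 / layer$d_in)),
                       layer$d_in, layer$d_out),
            b = numeric(layer$d_out))
        }
      }
      out
    })
  } else {
    load_cnn_weights(config$weight_file, plan)
  }
  structure(list(weights = weights, plan = plan, config = config),
            class = "audio_cnn")
}

load_cnn_weights <- function(path, plan) {
  weights <- readRDS(path)
  for (layer in plan) {
    if (layer$type == "pool") next
    w <- weights[[layer$name]]
    if (is.null(w)) stop("weight file is missing layer ", layer$name, call. = FALSE)
    expect_dim <- if (layer$type == "conv") {
      c(9L * layer$c_in, layer$c_out)
    } else {
      c(layer$d_in, layer$d_out)
    }
    if (!identical(dim(w$W), as.integer(expect_dim)) ||
        length(w$b) != expect_dim[2]) {
      stop(sprintf("weight shapes for layer %s do not match the architecture (need %d x %d)",
                   layer$name, expect_dim[1], expect_dim[2]), call. = FALSE)
    }
  }
  weights
}

#' @export
print.audio_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$weights, function(w) length(w$W) + length(w$b), numeric(1)))
  cat(sprintf("<audio_cnn> %s weights, %.1fM parameters, 96 x 64 input\n",
              x$config$weight_source, n_par / 1e6))
  invisible(x)
}

# --- forward pass ------------------------------------------------------------

# Neighbor index map for 3x3 same-padded convolution at spatial size h x w.
# Position order within an image: row-major, index = (i-1)*w + j.
# Column `o` of the result holds, for each position, the linear index of the
# o-th neighbor, or NA where the neighbor falls outside (zero padding).
conv_index_map <- function(h, w) {
  pos_i <- rep(seq_len(h), each = w)
  pos_j <- rep(seq_len(w), times = h)
  offsets <- expand.grid(dy = -1:1, dx = -1:1)
  idx <- matrix(NA_integer_, nrow = h * w, ncol = 9L)
  for (o in seq_len(9L)) {
    ni <- pos_i + offsets$dy[o]
    nj <- pos_j + offsets$dx[o]
    ok <- ni >= 1L & ni <= h & nj >= 1L & nj <= w
    idx[ok, o] <- (ni[ok] - 1L) * w + nj[ok]
  }
  idx
}

# x: (B*h*w) x c_in activations, rows grouped by image then row-major
# position.  Returns (B*h*w) x c_out.
conv_forward <- function(x, h, w, b_size, wts, idx9) {
  c_in <- ncol(x)
  npos <- h * w
  X9 <- matrix(0, nrow = b_size * npos, ncol = 9L * c_in)
  base <- rep((seq_len(b_size) - 1L) * npos, each = npos)
  for (o in seq_len(9L)) {
    src <- idx9[, o]
    ok <- !is.na(src)
    rows_ok <- rep(ok, times = b_size)
    src_all <- base + rep(ifelse(ok, src, 1L), times = b_size)
    cols <- ((o - 1L) * c_in + 1L):(o * c_in)
    X9[rows_ok, cols] <- x[src_all[rows_ok], , drop = FALSE]
  }
  out <- X9 %*% wts$W
  out <- sweep(out, 2L, wts$b, `+`)
  out[out < 0] <- 0
  out
}

# Non-overlapping 2x2 max pooling: input (B*h*w) x c -> (B*(h/2)*(w/2)) x c.
pool_forward <- function(x, h, w, b_size) {
  h2 <- h %/% 2L
  w2 <- w %/% 2L
  pos_i <- rep(seq_len(h2), each = w2)
  pos_j <- rep(seq_len(w2), times = h2)
  base <- rep((seq_len(b_size) - 1L) * h * w, each = h2 * w2)
  tl <- base + rep((2L * pos_i - 2L) * w + (2L * pos_j - 1L), times = b_size)
  out <- pmax(x[tl, , drop = FALSE], x[tl + 1L, , drop = FALSE],
              x[tl + w, , drop = FALSE], x[tl + w + 1L, , drop = FALSE])
  out
}

# Flatten (B*h*w) x c rows into B x (h*w*c), channel-fastest within position.
flatten_batch <- function(x, npos, b_size) {
  a <- array(t(x), dim = c(ncol(x), npos, b_size))
  t(matrix(a, nrow = ncol(x) * npos))
}

forward_batch <- function(network, xin, b_size) {
  # xin: (B*96*64) x 1 matrix of spectrogram values in row-major position order
  plan <- network$plan
  wts <- network$weights
  acts <- list()
  x <- xin
  h <- CNN_INPUT_FRAMES; w <- CNN_INPUT_BANDS
  idx_cache <- list()
  for (layer in plan) {
    if (layer$type == "conv") {
      key <- paste(h, w)
      if (is.null(idx_cache[[key]])) idx_cache[[key]] <- conv_index_map(h, w)
      x <- conv_forward(x, h, w, b_size, wts[[layer$name]], idx_cache[[key]])
    } else if (layer$type == "pool") {
      x <- pool_forward(x, h, w, b_size)
      h <- h %/% 2L
      w <- w %/% 2L
    } else if (layer$type == "fc") {
      if (!is.null(dim(x)) && nrow(x) != b_size) {
        x <- flatten_batch(x, h * w, b_size)
      }
      x <- x %*% wts[[layer$name]]$W
      x <- sweep(x, 2L, wts[[layer$name]]$b, `+`)
      if (layer$name != "Predic") x[x < 0] <- 0
    }
    if (layer$name %in% ANALYZED_LAYERS) {
      acts[[layer$name]] <- if (layer$type == "fc") x else flatten_batch(x, h * w, b_size)
    }
  }
  acts
}

#' Forward pass returning the six analyzed layers
#'
#' Pushes one 96 x 64 log-mel spectrogram frame through the network and
#' returns the flattened activations of the six analyzed layers (Pool2,
#' Pool3, Conv4, Pool4, FC1, Embed).  Deterministic given the weights.
#'
#' @param network An `audio_cnn` from [build_network()].
#' @param mel A 96 x 64 numeric matrix (frames x mel bands), or a
#'   `mel_spectrogram` whose `values` are 96 x 64.
#' @return Named list of numeric vectors, one per analyzed layer, with
#'   lengths 49152, 24576, 49152, 12288, 4096 and 128.
#' @export
forward_layers <- function(network, mel) {
  if (!inherits(network, "audio_cnn")) stop("`network` must be an audio_cnn")
  if (inherits(mel, "mel_spectrogram")) mel <- mel$values
  if (!is.matrix(mel) || !all(dim(mel) == c(CNN_INPUT_FRAMES, CNN_INPUT_BANDS))) {
    stop(sprintf("input must be %d x %d (got %s)", CNN_INPUT_FRAMES,
                 CNN_INPUT_BANDS, paste(dim(mel), collapse = " x ")), call. = FALSE)
  }
  xin <- matrix(as.numeric(t(mel)), ncol = 1L)   # row-major positions
  acts <- forward_batch(network, xin, 1L)
  lapply(acts, function(a) as.numeric(a[1L, ]))
}

#' Per-layer activation time series for a scene
#'
#' Slides a 960 ms analysis window over the scene in steps of `hop_s`,
#' pushes each window's 96 x 64 log-mel spectrogram through the network,
#' and collects one flattened activation vector per window and layer.
#' Each frame is stamped with its window END time, so activity at time t
#' only reflects audio up to t (causality for the surprisal history).
#'
#' @param network An `audio_cnn`.
#' @param scene An `audio_scene` of at least 960 ms, or a precomputed
#'   `mel_spectrogram` of the whole scene.
#' @param hop_s Window hop in seconds; must be a multiple of the 10 ms mel
#'   hop (default 0.1, giving a 10 Hz activation rate).
#' @param layers Which analyzed layers to return (default all six).
#' @param batch Windows per forward batch (default 16).
#' @return An object of class `layer_activations`: list with `layers`
#'   (named list of frames x width matrices), `time` (window end times, s)
#'   and `frame_rate` (`1 / hop_s`).
#' @export
activation_timeseries <- function(network, scene, hop_s = 0.1,
                                  layers = ANALYZED_LAYERS, batch = 16L) {
  layers <- match.arg(layers, ANALYZED_LAYERS, several.ok = TRUE)
  mel <- if (inherits(scene, "mel_spectrogram")) scene else compute_mel_spectrogram(scene)
  hop_frames <- hop_s * mel$frame_rate
  if (abs(hop_frames - round(hop_frames)) > 1e-8) {
    stop("`hop_s` must be a multiple of the 10 ms spectrogram hop", call. = FALSE)
  }
  hop_frames <- as.integer(round(hop_frames))
  n_mel <- nrow(mel$values)
  if (n_mel < CNN_INPUT_FRAMES) stop("scene shorter than one 960 ms window", call. = FALSE)
  n_win <- (n_mel - CNN_INPUT_FRAMES) %/% hop_frames + 1L
  widths <- cnn_layer_widths()
  out <- lapply(layers, function(l) matrix(0, nrow = n_win, ncol = widths[[l]]))
  names(out) <- layers
  done <- 0L
  while (done < n_win) {
    b <- min(batch, n_win - done)
    xin <- matrix(0, nrow = b * CNN_INPUT_FRAMES * CNN_INPUT_BANDS, ncol = 1L)
    for (j in seq_len(b)) {
      k <- done + j
      i0 <- (k - 1L) * hop_frames + 1L
      seg <- mel$values[i0:(i0 + CNN_INPUT_FRAMES - 1L), , drop = FALSE]
      rows <- ((j - 1L) * CNN_INPUT_FRAMES * CNN_INPUT_BANDS + 1L):
        (j * CNN_INPUT_FRAMES * CNN_INPUT_BANDS)
      xin[rows, 1L] <- as.numeric(t(seg))
    }
    acts <- forward_batch(network, xin, b)
    for (l in layers) out[[l]][(done + 1L):(done + b), ] <- acts[[l]]
    done <- done + b
  }
  window_s <- CNN_INPUT_FRAMES * mel$frame_hop_s
  structure(
    list(layers = out,
         time = window_s + (seq_len(n_win) - 1L) * hop_s,
         frame_rate = 1 / hop_s),
    class = "layer_activations"
  )
}

#' @export
print.layer_activations <- function(x, ...) {
  cat(sprintf("<layer_activations> %d frames @ %g Hz; layers: %s\n",
              length(x$time), x$frame_rate,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}
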