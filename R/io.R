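# Plain-format readers and writers: PCM WAV for scenes, tab-separated text
# for curves, feature tables, event lists and channel matrices.

#' Write an audio scene as a 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and scaled to the 16-bit integer range.
#' If the scene carries annotations, a sidecar tab-separated file
#' `<path>.events.tsv` is written with columns `onset_s`, `category`,
#' `level_db`, `duration_s`.
#'
#' @param scene An `audio_scene`.
#' @param path Output path.
#' @param sidecar Write the annotation sidecar when annotations exist
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_scene_wav <- function(scene, path, sidecar = TRUE) {
  if (!inherits(scene, "audio_scene")) stop("`scene` must be an audio_scene")
  x <- pmax(-1, pmin(1, scene$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  sr <- as.integer(round(scene$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(2L * sr, con, size = 4, endian = "little")     # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  if (sidecar && !is.null(scene$annotations) && nrow(scene$annotations) > 0) {
    write_events(scene$annotations, paste0(path, ".events.tsv"))
  }
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file as an audio scene
#'
#' Minimal RIFF reader for the files [write_scene_wav()] produces (and any
#' other mono 16-bit PCM WAV).  If `<path>.events.tsv` exists it is read
#' as the annotation table.
#'
#' @param path WAV file path.
#' @return An `audio_scene`.
#' @export
read_scene_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path, call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path, call. = FALSE)
  sr <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported", call. = FALSE)
      n_channels <- fmt[2]
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16L))
    } else if (identical(id, "data")) {
      if (is.null(bits) || bits != 16L) stop("only 16-bit PCM is supported", call. = FALSE)
      samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  if (n_channels != 1L) stop("only mono WAV is supported", call. = FALSE)
  ann <- NULL
  sidecar <- paste0(path, ".events.tsv")
  if (file.exists(sidecar)) ann <- read_events(sidecar)
  audio_scene(samples / 32767, sr, annotations = ann)
}

#' Write / read a salient-event table (tab-separated)
#'
#' @param events Tibble with at least `onset_s` or `time_s` plus any of
#'   `category`, `level_db`, `duration_s`, `strength`.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write a multi-track time-series table as tab-separated text
#'
#' One row per time sample; the first column is `time` in seconds and the
#' header row names the tracks.  The sampling rate is recorded on a
#' leading `# rate=<Hz>` comment line.
#'
#' @param x Tibble with a `time` column and one column per track.
#' @param path File path.
#' @param rate Sampling rate in Hz recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(x, path, rate = NULL) {
  if (is.null(rate)) rate <- attr(x, "rate")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(rate)) writeLines(sprintf("# rate=%g", rate), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_table
#' @export
read_track_table <- function(path) {
  first <- readLines(path, n = 1L)
  rate <- NULL
  skip <- 0L
  if (startsWith(first, "# rate=")) {
    rate <- as.numeric(sub("# rate=", "", first))
    skip <- 1L
  }
  out <- tibble::as_tibble(read.delim(path, sep = "\t", skip = skip,
                                      stringsAsFactors = FALSE))
  attr(out, "rate") <- rate
  out
}

#' Write / read a channels-by-samples signal matrix
#'
#' Stored as tab-separated text with samples in rows and channels in
#' columns; the header row carries channel names and a leading
#' `# rate=<Hz>` comment records the sampling rate.
#'
#' @param signal Numeric matrix, channels x samples.
#' @param rate Sampling rate in Hz.
#' @param path File path.
#' @return `path` (write) or a channels-x-samples matrix with attribute
#'   `"rate"` (read).
#' @export
write_signal_matrix <- function(signal, rate, path) {
  if (is.null(rownames(signal))) {
    rownames(signal) <- sprintf("ch%02d", seq_len(nrow(signal)))
  }
  df <- as.data.frame(t(signal))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate=%g", rate), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# rate=")) stop("missing '# rate=' header in ", path)
  rate <- as.numeric(sub("# rate=", "", first))
  df <- read.delim(path, sep = "\t", skip = 1L)
  sig <- t(as.matrix(df))
  attr(sig, "rate") <- rate
  sig
}

#' Read an electrode-group mapping
#'
#' Two tab-separated columns (`channel`, `group`), no fixed cap layout is
#' assumed: group membership (e.g. 21 electrodes near Fz as `frontal`,
#' 23 near Cz as `central`) is whatever the file says.
#'
#' @param path File path.
#' @return Named character vector mapping channel name to group.
#' @export
read_electrode_groups <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("channel", "group") %in% names(df))) {
    stop("electrode group file needs columns `channel` and `group`", call. = FALSE)
  }
  setNames(df$group, df$channel)
}
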