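#' Read a mono RIFF WAV file
#'
#' Reads PCM 16-bit, PCM 24-bit and IEEE float32 mono WAV files into a
#' [song_recording()]. Stereo (or any multi-channel) files are rejected:
#' the analysis operates on single-microphone recordings.
#'
#' @param path Path to a `.wav` file.
#' @param song_type `"calling"` or `"courtship"`; stored as metadata.
#' @param individual_id Identifier stored as metadata; defaults to the
#'   file name without extension.
#' @return A `song_recording` object (see [song_recording()]).
#' @export
read_wav <- function(path, song_type = "calling", individual_id = NULL) {
  if (!file.exists(path)) abort(paste0("WAV file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(paste0("not a RIFF file: ", path))
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(paste0("not a WAVE file: ", path))

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels   = readBin(raw[3:4], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        sample_rate  = readBin(raw[5:8], "integer", 1, size = 4,
                               endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, size = 2,
                               endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort("malformed WAV: data chunk before fmt chunk")
      samples <- .decode_wav_data(readBin(con, "raw", size), fmt)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) abort(paste0("no data chunk found in ", path))
  if (fmt$n_channels != 1L) {
    abort(paste0("expected mono audio but ", path, " has ",
                 fmt$n_channels, " channels"))
  }
  song_recording(samples, sample_rate = fmt$sample_rate,
                 song_type = song_type,
                 individual_id = individual_id %||%
                   sub("\\.[Ww][Aa][Vv]$", "", basename(path)))
}

.decode_wav_data <- function(raw, fmt) {
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(raw, "integer", length(raw) %/% 2L, size = 2,
            endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    n <- length(raw) %/% 3L
    b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    v / 8388608
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(raw, "double", length(raw) %/% 4L, size = 4, endian = "little")
  } else {
    abort(paste0("unsupported WAV encoding: format ", fmt$audio_format,
                 ", ", fmt$bits, " bits (PCM16, PCM24, float32 supported)"))
  }
}

#' Write a mono WAV file
#'
#' @param recording A `song_recording`.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path, bits = 16) {
  stopifnot(inherits(recording, "song_recording"))
  x <- recording$samples
  fs <- recording$sample_rate
  if (bits == 16) {
    fmt_code <- 1L
    data_raw <- writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)),
                         raw(), size = 2, endian = "little")
  } else if (bits == 32) {
    fmt_code <- 3L
    data_raw <- writeBin(as.double(x), raw(), size = 4, endian = "little")
  } else {
    abort("bits must be 16 or 32")
  }
  block_align <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(data_raw)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(data_raw)), con, size = 4, endian = "little")
  writeBin(data_raw, con)
  invisible(path)
}
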