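#' Construct a song recording
#'
#' A `song_recording` bundles a mono waveform with its sample rate and
#' metadata. Samples are expected in `[-1, 1]` (full scale).
#'
#' @param samples Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param song_type `"calling"` or `"courtship"`.
#' @param individual_id Identifier string.
#' @return An object of class `song_recording`.
#' @export
song_recording <- function(samples, sample_rate, song_type = "calling",
                           individual_id = "unknown") {
  if (!is.numeric(samples) || length(samples) == 0L) {
    abort("samples must be a non-empty numeric vector")
  }
  if (any(!is.finite(samples))) abort("samples contain non-finite values")
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("sample_rate must be a positive number (Hz)")
  }
  song_type <- match.arg(song_type, c("calling", "courtship"))
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         song_type = song_type, individual_id = as.character(individual_id)),
    class = "song_recording"
  )
}

#' @export
print.song_recording <- function(x, ...) {
  cat(sprintf("<song_recording> %s (%s): %d samples @ %g Hz (%.3f s)\n",
              x$individual_id, x$song_type, length(x$samples),
              x$sample_rate, length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Default frequency band table
#'
#' Six contiguous half-open frequency bands (A-F) over 0-20 kHz used for the
#' band-relative amplitude and frequency-evenness features. The defaults
#' follow the tuning structure of the cricket auditory system: a low band
#' around the ancestral carrier (~4-5 kHz), mid bands covering the derived
#' song frequencies, and a high band reaching into the ultrasound-sensitive
#' range. Band edges are configuration, not a constant of the method; every
#' feature table records the band table used.
#'
#' @return A tibble with columns `band`, `lo_hz`, `hi_hz`.
#' @export
default_bands <- function() {
  tibble(
    band  = c("A", "B", "C", "D", "E", "F"),
    lo_hz = c(0, 3500, 6500, 9500, 12500, 16000),
    hi_hz = c(3500, 6500, 9500, 12500, 16000, 20000)
  )
}

.validate_bands <- function(bands) {
  bands <- as_tibble(bands)
  if (!all(c("band", "lo_hz", "hi_hz") %in% names(bands))) {
    abort("bands must have columns band, lo_hz, hi_hz")
  }
  if (nrow(bands) != 6L) abort("exactly six frequency bands are required")
  if (any(diff(bands$lo_hz) <= 0)) abort("bands must be sorted by lo_hz")
  if (any(bands$hi_hz <= bands$lo_hz)) abort("each band needs hi_hz > lo_hz")
  if (any(abs(bands$hi_hz[-6] - bands$lo_hz[-1]) > 1e-9)) {
    abort("bands must be contiguous (hi_hz of one band = lo_hz of the next)")
  }
  bands
}

#' Welch-averaged power spectrum
#'
#' Hann-tapered, overlapped, averaged periodogram of a recording. The power
#' is normalised so that the sum over all bins approximates the mean square
#' of the waveform (taper-corrected), giving Parseval consistency.
#'
#' @param recording A [song_recording()].
#' @param window_size Segment length in samples; a power of two, >= 16.
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return A `power_spectrum` object: list with `frequencies` (Hz, from 0 to
#'   Nyquist), `power` (non-negative), `window_size`, `window`, `sample_rate`.
#' @export
power_spectrum <- function(recording, window_size = 256, overlap = 0.5) {
  stopifnot(inherits(recording, "song_recording"))
  n <- as.integer(window_size)
  if (n < 16L || bitwAnd(n, n - 1L) != 0L) {
    abort("window_size must be a power of two >= 16")
  }
  if (overlap < 0 || overlap >= 1) abort("overlap must be in [0, 1)")
  x <- recording$samples
  if (any(!is.finite(x))) abort("recording contains non-finite samples")
  if (length(x) < n) {
    abort(paste0("recording has ", length(x), " samples but at least ",
                 n, " (one full analysis window) are required"))
  }
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / n))  # periodic Hann
  hop <- max(1L, as.integer(round(n * (1 - overlap))))
  starts <- seq(1L, length(x) - n + 1L, by = hop)
  acc <- numeric(n %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + n - 1L)] * w
    sp <- abs(fft(seg))^2 / (n * sum(w^2))
    half <- sp[seq_len(n %/% 2L + 1L)]
    # fold the negative frequencies back (DC and Nyquist are unique)
    half[2:(n %/% 2L)] <- 2 * half[2:(n %/% 2L)]
    acc <- acc + half
  }
  structure(
    list(frequencies = (0:(n %/% 2L)) * recording$sample_rate / n,
         power = acc / length(starts),
         window_size = n, window = "hann",
         sample_rate = recording$sample_rate),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, 0-%g Hz, %s window %d\n",
              length(x$frequencies), max(x$frequencies), x$window,
              x$window_size))
  invisible(x)
}

#' Dominant frequency of a power spectrum
#'
#' Frequency of the bin with maximum power. Ties are broken toward the
#' lowest frequency.
#'
#' @param spectrum A `power_spectrum`.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (all(spectrum$power <= 0)) abort("no signal: spectrum has no nonzero power")
  peak <- which(spectrum$power == max(spectrum$power))[1L]
  spectrum$frequencies[peak]
}

#' Band-relative amplitudes
#'
#' Integrates spectral power over six half-open frequency bands
#' `[lo_hz, hi_hz)`, converts each band's power to an RMS amplitude, and
#' normalises by the sum of the six band amplitudes.
#'
#' @param recording A [song_recording()] (or a precomputed `power_spectrum`).
#' @param bands Band table as from [default_bands()].
#' @param window_size,overlap Spectral settings used when `recording` is a
#'   waveform.
#' @return Named numeric vector of six proportions summing to 1.
#' @export
band_relative_amplitudes <- function(recording, bands = default_bands(),
                                     window_size = 256, overlap = 0.5) {
  bands <- .validate_bands(bands)
  spec <- if (inherits(recording, "power_spectrum")) recording else
    power_spectrum(recording, window_size, overlap)
  if (max(bands$hi_hz) > max(spec$frequencies) * (1 + 1e-9)) {
    abort(paste0("sample rate too low: bands extend to ", max(bands$hi_hz),
                 " Hz but Nyquist is ", max(spec$frequencies), " Hz"))
  }
  amp <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- spec$frequencies >= bands$lo_hz[i] & spec$frequencies < bands$hi_hz[i]
    sqrt(sum(spec$power[sel]))
  }, numeric(1))
  if (sum(amp) <= 0) abort("zero total band energy: cannot form proportions")
  setNames(amp / sum(amp), bands$band)
}

#' Frequency evenness
#'
#' The broadbandedness statistic: the additive inverse of the standard
#' deviation (sample, n-1 denominator by default) of the six band-relative
#' amplitudes. 0 for a perfectly even spectrum, more negative for more
#' tonal songs.
#'
#' @param rel_amps Six proportions summing to 1.
#' @param denominator `"sample"` (n-1) or `"population"` (n).
#' @return A score in `(-1, 0]`.
#' @export
frequency_evenness <- function(rel_amps, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  if (length(rel_amps) != 6L) {
    abort(paste0("expected 6 relative amplitudes, got ", length(rel_amps)))
  }
  if (abs(sum(rel_amps) - 1) > 1e-6) {
    abort("relative amplitudes must sum to 1")
  }
  s <- sd(rel_amps)
  if (denominator == "population") s <- s * sqrt(5 / 6)
  -s
}

#' Extract the nine song features from a recording
#'
#' Computes the nine acoustic characteristics of one song: dominant
#' frequency, overall RMS amplitude in dB (relative to full scale by
#' default), the six band-relative amplitudes, and frequency evenness.
#'
#' @param recording A [song_recording()].
#' @param bands Band table (see [default_bands()]).
#' @param window_size,overlap Spectral analysis settings.
#' @param db_reference Amplitude reference for the dB conversion (1 = full
#'   scale; supply a calibration constant for SPL-calibrated recordings).
#' @return A one-row tibble with `individual_id`, `song_type`,
#'   `dominant_frequency`, `amplitude_db`, `rel_amplitude_A` ..
#'   `rel_amplitude_F`, and `frequency_evenness`.
#' @export
extract_song_features <- function(recording, bands = default_bands(),
                                  window_size = 256, overlap = 0.5,
                                  db_reference = 1) {
  stopifnot(inherits(recording, "song_recording"))
  spec <- power_spectrum(recording, window_size, overlap)
  rel <- band_relative_amplitudes(spec, bands)
  rms <- sqrt(mean(recording$samples^2))
  if (rms <= 0) abort("silent recording: RMS amplitude is zero")
  out <- tibble(
    individual_id = recording$individual_id,
    song_type = recording$song_type,
    dominant_frequency = dominant_frequency(spec),
    amplitude_db = 20 * log10(rms / db_reference)
  )
  out[paste0("rel_amplitude_", names(rel))] <- as.list(unname(rel))
  out$frequency_evenness <- frequency_evenness(rel)
  attr(out, "bands") <- bands
  out
}

#' Song feature column names
#'
#' The nine per-song feature columns produced by [extract_song_features()].
#' @return Character vector of length 9.
#' @export
song_feature_names <- function() {
  c("dominant_frequency", "amplitude_db",
    paste0("rel_amplitude_", c("A", "B", "C", "D", "E", "F")),
    "frequency_evenness")
}

#' @export
autoplot.power_spectrum <- function(object, ...) {
  df <- tibble(frequency_khz = object$frequencies / 1000,
               power_db = 10 * log10(pmax(object$power, 1e-12)))
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency_khz, .data$power_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (kHz)", y = "Power (dB)",
                  title = "Welch power spectrum") +
    ggplot2::theme_minimal()
}
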