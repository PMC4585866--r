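# Minimal PCM RIFF/WAVE I/O. Only uncompressed integer PCM is supported;
# that is the format of the experiment's deposited target recordings
# (48 kHz, 16 bit).

#' Read a PCM WAV file
#'
#' Reads an uncompressed PCM RIFF/WAVE file. Multi-channel files are averaged
#' to mono. Samples are returned on \[-1, 1\].
#'
#' @param path path to a `.wav` file.
#' @return list with `samples` (numeric) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little") # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little") # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (audio_format != 1L) {
        stop("unsupported WAV encoding (only uncompressed PCM is handled)")
      }
      if (!bits %in% c(16L, 8L)) stop("unsupported PCM bit depth: ", bits)
      fmt <- list(n_channels = n_channels, sample_rate = sample_rate,
                  bits = bits)
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$bits == 16L) {
        n <- sz %/% 2
        raw <- readBin(con, "integer", n, size = 2, signed = TRUE,
                       endian = "little")
        samples <- raw / 32768
      } else {
        raw <- readBin(con, "integer", sz, size = 1, signed = FALSE)
        samples <- (raw - 128) / 128
      }
      break
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (fmt$n_channels > 1L) {
    samples <- rowMeans(matrix(samples, ncol = fmt$n_channels, byrow = TRUE))
  }
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' Write a waveform as 16-bit PCM WAV
#'
#' The waveform is peak-scaled to 0.999 full scale before quantization, so
#' arbitrary-RMS input is accepted; re-reading and RMS-normalizing recovers
#' the original normalized waveform up to PCM quantization error.
#'
#' @param samples numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  peak <- max(abs(samples))
  if (!is.finite(peak) || peak == 0) stop("refusing to write an all-zero waveform")
  x <- as.integer(round(samples / peak * 0.999 * 32767))
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Load a WAV file as a target signal
#'
#' Reads a PCM WAV file, RMS-normalizes it, and wraps it as a
#' [target_signal()]. Label and timing metadata are taken from the
#' arguments (the deposited recordings encode them in filenames, which the
#' caller can parse).
#'
#' @param path path to a PCM WAV file.
#' @param consonant_label `"da"` or `"ga"` (or `NA`).
#' @param context_label `"l"` or `"r"` (first-syllable coda; or `NA`).
#' @param syllable2_onset second-syllable onset in seconds (or `NA`).
#' @return a `target_signal`.
#' @export
load_wav <- function(path, consonant_label = NA_character_,
                     context_label = NA_character_,
                     syllable2_onset = NA_real_) {
  w <- read_wav(path)
  if (all(w$samples == 0)) {
    stop("all-zero WAV file: RMS normalization is undefined")
  }
  target_signal(samples = w$samples, sample_rate = w$sample_rate,
                consonant_label = consonant_label,
                context_label = context_label,
                syllable2_onset = syllable2_onset)
}
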