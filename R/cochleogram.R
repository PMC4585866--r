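# Cochleogram front-end: gammatone-style filterbank, half-wave
# rectification, low-pass envelope smoothing, power-law compression, and
# frame averaging onto the analysis grid (by default 15.6 ms frames and 54
# geometrically spaced channels between 96 and 7760 Hz, the grid on which
# classification images are estimated).

#' Construct an auditory filterbank
#'
#' Each channel is an all-pole gammatone approximation: a cascade of four
#' identical two-pole resonators. Pole damping is set so the measured
#' -3 dB bandwidth of the cascade equals `f_c / q` (quality factor `q`).
#' Center frequencies are geometrically spaced between `f_lo` and `f_hi`
#' inclusive.
#'
#' @param sample_rate sampling rate in Hz.
#' @param n_channels number of spectral channels.
#' @param f_lo,f_hi lowest and highest center frequency in Hz.
#' @param q quality factor (center frequency over -3 dB bandwidth).
#' @param time_bin analysis frame duration in seconds.
#' @param compression power-law compression exponent applied to the
#'   smoothed envelope.
#' @param env_cutoff envelope low-pass cutoff in Hz.
#' @return object of class `filterbank`.
#' @export
make_filterbank <- function(sample_rate = 48000, n_channels = 54,
                            f_lo = 96, f_hi = 7760, q = 8,
                            time_bin = 0.0156, compression = 0.3,
                            env_cutoff = 64) {
  n_channels <- as.integer(n_channels)
  stopifnot(sample_rate > 0, n_channels >= 1, f_lo > 0, f_hi > f_lo, q > 0)
  if (f_hi >= sample_rate / 2) {
    stop("top center frequency must be below the Nyquist frequency")
  }
  cf <- f_lo * (f_hi / f_lo)^(seq(0, n_channels - 1) / max(1, n_channels - 1))
  if (n_channels == 1) cf <- f_lo
  # -3 dB full width of a cascade of 4 identical 2-pole resonators with
  # single-stage -3 dB width b: 2*(b/2)*sqrt(2^(1/4)-1); solve for b.
  b_single <- (cf / q) / sqrt(2^(1 / 4) - 1)
  t_samp <- 1 / sample_rate
  r <- exp(-pi * b_single * t_samp)
  theta <- 2 * pi * cf * t_samp
  a1 <- -2 * r * cos(theta)
  a2 <- r^2
  # per-channel gain so the 4-stage cascade has unit response at cf
  h1 <- Mod(1 / (1 + a1 * exp(-1i * theta) + a2 * exp(-2i * theta)))
  gain_stage <- (1 / h1)                 # applied once per stage
  env_lp <- signal::butter(2, min(env_cutoff, 0.45 * sample_rate / 2) /
                                (sample_rate / 2), type = "low")
  structure(list(
    sample_rate = sample_rate, n_channels = n_channels,
    center_freqs = cf, q = q, a1 = a1, a2 = a2, gain_stage = gain_stage,
    time_bin = time_bin, compression = compression,
    env_cutoff = env_cutoff, env_lp = env_lp,
    note = "Lyon-model stand-in; 'overlapping = 40%' recorded, not modeled"
  ), class = "filterbank")
}

#' Filterbank magnitude response
#'
#' Evaluates the cascaded transfer function of each channel at the given
#' frequencies (useful for verifying center frequencies and bandwidths).
#'
#' @param fb a `filterbank`.
#' @param freqs frequencies in Hz.
#' @return matrix `length(freqs) x n_channels` of linear magnitudes.
#' @export
filterbank_response <- function(fb, freqs) {
  w <- 2 * pi * freqs / fb$sample_rate
  z1 <- exp(-1i * w)
  sapply(seq_len(fb$n_channels), function(k) {
    h <- fb$gain_stage[k] / (1 + fb$a1[k] * z1 + fb$a2[k] * z1^2)
    Mod(h)^4
  })
}

#' Compute a cochleogram
#'
#' Per channel: bandpass filtering (four cascaded resonator stages),
#' half-wave rectification, low-pass envelope smoothing, power-law
#' compression, then averaging into `time_bin` frames. Trailing partial
#' frames are dropped, so a 680 ms input on the default grid yields a
#' 43 x 54 matrix.
#'
#' @param x a waveform: numeric vector, `target_signal`, or
#'   `stimulus_mix` (whose pre-analysis fade-in is excluded).
#' @param fb a `filterbank` matching the waveform's sample rate.
#' @return object of class `cochleogram`: list with `values`
#'   (`n_time x n_freq` matrix), `time_bin`, `center_freqs`, `times`
#'   (frame centers, seconds), `source_ref`.
#' @export
compute_cochleogram <- function(x, fb) {
  source_ref <- NA_character_
  if (inherits(x, "target_signal")) {
    if (x$sample_rate != fb$sample_rate) stop("sample-rate mismatch")
    source_ref <- x$id
    x <- x$samples
  } else if (inherits(x, "stimulus_mix")) {
    if (!is.null(x$sample_rate) && x$sample_rate != fb$sample_rate) {
      stop("sample-rate mismatch")
    }
    source_ref <- x$target_ref
    x <- x$samples[x$analysis_start:length(x$samples)]
  }
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty waveform")
  frame_len <- fb$time_bin * fb$sample_rate
  n_frames <- floor(length(x) / frame_len)
  if (n_frames < 1) stop("waveform shorter than one analysis frame")
  fidx <- floor((seq_along(x) - 1) / frame_len) + 1
  fidx[fidx > n_frames] <- 0L   # trailing partial frame dropped
  # the smoothed envelope is oversampled at audio rate: compress/average
  # on a decimated grid well above the envelope bandwidth
  decim <- max(1L, min(floor(frame_len / 8),
                       floor(fb$sample_rate / (16 * fb$env_cutoff))))
  vals <- .cochleogram_core(x, fb$a1, fb$a2, fb$gain_stage,
                            as.numeric(fb$env_lp$b), as.numeric(fb$env_lp$a),
                            as.integer(fidx), as.integer(n_frames),
                            fb$compression, as.integer(decim))
  structure(list(
    values = vals,
    time_bin = fb$time_bin,
    center_freqs = fb$center_freqs,
    times = (seq_len(n_frames) - 0.5) * fb$time_bin,
    source_ref = source_ref
  ), class = "cochleogram")
}

#' Flatten a cochleogram to a pixel vector
#'
#' Fixed row-major (time-major) flattening: pixel 1 is (t=1, f=1), pixel 2
#' is (t=1, f=2), and so on. [devectorize()] is its exact inverse.
#'
#' @param coch a `cochleogram` or an `n_time x n_freq` matrix.
#' @return numeric vector of length `n_time * n_freq`.
#' @export
vectorize <- function(coch) {
  m <- if (inherits(coch, "cochleogram")) coch$values else coch
  as.vector(t(m))
}

#' Restore a pixel vector to its time-frequency matrix
#'
#' @param v pixel vector from [vectorize()].
#' @param n_time,n_freq grid dimensions.
#' @return `n_time x n_freq` matrix.
#' @export
devectorize <- function(v, n_time, n_freq) {
  stopifnot(length(v) == n_time * n_freq)
  matrix(v, nrow = n_time, byrow = TRUE)
}
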