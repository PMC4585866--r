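# Synthetic VCCV targets and white-noise maskers.
#
# The categorization task contrasts the final syllable /da/ vs /ga/ of a
# VCCV non-word (e.g. /alda/). The two stops differ in the onset
# configuration of the second and third formant transitions: distant F2/F3
# onsets for /da/, close onsets for /ga/. The generator is a parametric
# source-filter synthesizer (pulse-train glottal source through a cascade
# of time-varying formant resonators), so the whole pipeline can be
# exercised without recorded speech.

#' Construct a target signal
#'
#' Wraps a waveform with its label and timing metadata and RMS-normalizes
#' it. `syllable2_onset` is the acoustic onset of the second syllable, the
#' landmark at which all four targets are aligned.
#'
#' @param samples numeric waveform (not all zero).
#' @param sample_rate sampling rate in Hz.
#' @param consonant_label `"da"` or `"ga"` (or `NA`).
#' @param context_label `"l"` or `"r"` (or `NA`).
#' @param syllable2_onset seconds (or `NA`).
#' @param id optional identifier.
#' @param formant_onsets optional named numeric (F1, F2, F3) at stop onset.
#' @return object of class `target_signal`.
#' @export
target_signal <- function(samples, sample_rate, consonant_label = NA_character_,
                          context_label = NA_character_,
                          syllable2_onset = NA_real_, id = NULL,
                          formant_onsets = NULL) {
  if (!is.na(consonant_label) && !consonant_label %in% c("da", "ga")) {
    stop("consonant_label must be 'da' or 'ga'")
  }
  if (!is.na(context_label) && !context_label %in% c("l", "r")) {
    stop("context_label must be 'l' or 'r'")
  }
  samples <- rms_normalize(as.numeric(samples))
  duration <- length(samples) / sample_rate
  if (!is.na(syllable2_onset) &&
      (syllable2_onset <= 0 || syllable2_onset >= duration)) {
    stop("syllable2_onset must lie strictly inside the stimulus duration")
  }
  structure(list(
    samples = samples,
    sample_rate = sample_rate,
    consonant_label = consonant_label,
    context_label = context_label,
    syllable2_onset = syllable2_onset,
    duration = duration,
    id = id %||% paste0("a", context_label, consonant_label),
    formant_onsets = formant_onsets
  ), class = "target_signal")
}

#' Default timing configuration for VCCV synthesis
#'
#' Defaults reproduce the experiment's equalized targets: 680 ms total
#' duration with the second-syllable onset at 328 ms for all four targets.
#' Internal segment boundaries (first vowel, first-syllable coda, closure
#' gap) scale with the onset time so reduced-scale targets keep the same
#' VCCV structure.
#'
#' @param duration total duration in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param syllable2_onset onset of the second syllable in seconds.
#' @param f0 glottal source fundamental in Hz.
#' @param vowel steady-state /a/ formants in Hz.
#' @param da_onsets,ga_onsets F1/F2/F3 onset frequencies of the stop
#'   transitions (distant F2/F3 for /da/, converged for /ga/).
#' @param transition_dur formant transition duration in seconds.
#' @return named list used by [synthesize_vccv()].
#' @export
vccv_timing <- function(duration = 0.680, sample_rate = 48000,
                        syllable2_onset = 0.328, f0 = 120,
                        vowel = c(F1 = 700, F2 = 1220, F3 = 2600),
                        da_onsets = c(F1 = 650, F2 = 1400, F3 = 2550),
                        ga_onsets = c(F1 = 650, F2 = 1950, F3 = 2050),
                        transition_dur = 0.075) {
  stopifnot(duration > 0, sample_rate > 0,
            syllable2_onset > 0, syllable2_onset < duration)
  list(duration = duration, sample_rate = sample_rate,
       syllable2_onset = syllable2_onset, f0 = f0, vowel = vowel,
       da_onsets = da_onsets, ga_onsets = ga_onsets,
       transition_dur = transition_dur)
}

# Cascade of two-pole resonators with time-varying center frequencies.
# freqs: n x k matrix of instantaneous formant frequencies (Hz);
# bandwidths: length-k (Hz). Plain biquad recursion per formant.
resonator_cascade <- function(source, freqs, bandwidths, sample_rate) {
  n <- length(source)
  k <- ncol(freqs)
  t_samp <- 1 / sample_rate
  r <- exp(-pi * bandwidths * t_samp)
  ct <- cos(2 * pi * freqs * t_samp)      # n x k
  y <- source
  for (j in seq_len(k)) {
    a1 <- 2 * r[j] * ct[, j]
    a2 <- r[j]^2
    g <- (1 - r[j])                        # rough gain equalization
    out <- numeric(n)
    y1 <- 0; y2 <- 0
    for (i in seq_len(n)) {
      v <- g * y[i] + a1[i] * y1 - a2 * y2
      out[i] <- v
      y2 <- y1
      y1 <- v
    }
    y <- out
  }
  y
}

# Glottal-like pulse train: impulse train at f0 through a one-pole low-pass
# (spectral tilt).
glottal_source <- function(n, f0, sample_rate) {
  src <- numeric(n)
  period <- sample_rate / f0
  src[pmin(n, unique(round(seq(1, n, by = period))))] <- 1
  stats::filter(src, 0.96, method = "recursive")
}

#' Synthesize a VCCV target
#'
#' Source-filter synthesis of one of the four targets (/alda/, /alga/,
#' /arda/, /arga/). Segments: steady first vowel /a/; first-syllable coda
#' (voiced lateral for `"l"`, band-limited frication noise for `"r"`); a
#' silent closure gap; then the stop burst at exactly `syllable2_onset`
#' followed by formant transitions into the second /a/. The /da/ and /ga/
#' variants differ only in their F2/F3 transition-onset frequencies.
#'
#' @param consonant_label `"da"` or `"ga"`.
#' @param context_label `"l"` or `"r"`.
#' @param timing timing configuration from [vccv_timing()].
#' @param seed integer seed for the stochastic components (frication and
#'   burst noise); synthesis is deterministic given the seed.
#' @return a `target_signal`.
#' @export
synthesize_vccv <- function(consonant_label = c("da", "ga"),
                            context_label = c("l", "r"),
                            timing = vccv_timing(), seed = 1L) {
  consonant_label <- match.arg(consonant_label)
  context_label <- match.arg(context_label)
  fs <- timing$sample_rate
  nyq <- fs / 2
  onsets <- if (consonant_label == "da") timing$da_onsets else timing$ga_onsets
  if (any(c(timing$vowel, onsets) >= nyq)) {
    stop("formant frequency at or above Nyquist (", nyq, " Hz)")
  }
  n <- round(timing$duration * fs)
  t2 <- timing$syllable2_onset
  # segment boundaries in samples (closure gap is exact digital silence so
  # the second-syllable onset is measurable to the sample)
  i_v1_end <- round(0.656 * t2 * fs)
  i_c1_end <- round(0.884 * t2 * fs)
  i_onset <- round(t2 * fs)               # first syllable-2 sample is i_onset+1
  n_burst <- max(4L, round(0.006 * fs))
  n_trans <- round(min(timing$transition_dur,
                       0.4 * (timing$duration - t2)) * fs)
  n_fadeout <- round(min(0.025, 0.05 * timing$duration) * fs)
  bw <- c(90, 110, 170)

  out <- numeric(n)
  with_seed(derive_seed(seed, 7L), {
    # first vowel /a/
    nv <- i_v1_end
    fr <- matrix(rep(timing$vowel, each = nv), nrow = nv)
    v1 <- resonator_cascade(glottal_source(nv, timing$f0, fs), fr, bw, fs)
    # amplitude rise at stimulus start, gentle fall into the coda
    env <- pmin(1, seq_len(nv) / (0.015 * fs)) *
      rev(pmin(1, 0.3 + seq_len(nv) / (0.2 * nv)))
    out[seq_len(nv)] <- v1 * env

    # first-syllable coda
    nc <- i_c1_end - i_v1_end
    if (context_label == "l") {
      lat <- c(F1 = 360, F2 = 1050, F3 = min(2800, 0.9 * nyq))
      fr <- matrix(rep(lat, each = nc), nrow = nc)
      coda <- resonator_cascade(glottal_source(nc, timing$f0, fs), fr, bw, fs)
      coda <- 0.5 * coda / max(rms(coda), 1e-12)
    } else {
      fric <- rnorm(nc)
      fr <- matrix(rep(c(min(2500, 0.7 * nyq)), nc), nrow = nc)
      coda <- resonator_cascade(fric, fr, 1200, fs)
      coda <- 0.35 * coda / max(rms(coda), 1e-12)
    }
    out[i_v1_end + seq_len(nc)] <- coda * rms(v1 * env)

    # closure: exact silence in (i_c1_end, i_onset]

    # burst + transition + steady second vowel
    n2 <- n - i_onset
    burst <- numeric(n2)
    burst[1] <- 1
    burst[seq_len(n_burst)] <- burst[seq_len(n_burst)] +
      0.8 * rnorm(n_burst) * exp(-seq_len(n_burst) / (n_burst / 3))
    voiced <- glottal_source(n2, timing$f0, fs)
    voiced[seq_len(min(n_burst, n2))] <- 0
    src2 <- burst + voiced
    frac <- pmin(1, (seq_len(n2) - 1) / max(n_trans, 1))
    fr2 <- sapply(1:3, function(j) onsets[j] + frac * (timing$vowel[j] - onsets[j]))
    v2 <- resonator_cascade(src2, fr2, bw, fs)
    env2 <- rep(1, n2)
    if (n_fadeout > 0 && n_fadeout < n2) {
      env2[(n2 - n_fadeout + 1):n2] <- seq(1, 0, length.out = n_fadeout)
    }
    v2 <- v2 * env2
    # guarantee a non-zero first sample at the onset landmark
    if (v2[1] == 0) v2[1] <- 1e-6
    out[i_onset + seq_len(n2)] <- v2 * rms(v1 * env) / max(rms(v2), 1e-12)
  })

  target_signal(samples = out, sample_rate = fs,
                consonant_label = consonant_label,
                context_label = context_label,
                syllable2_onset = i_onset / fs,
                formant_onsets = onsets)
}

#' The four default VCCV targets
#'
#' @param timing timing configuration from [vccv_timing()].
#' @param seed integer seed.
#' @return named list of four `target_signal`s (/alda/, /alga/, /arda/,
#'   /arga/).
#' @export
default_targets <- function(timing = vccv_timing(), seed = 1L) {
  combos <- expand.grid(context = c("l", "r"), consonant = c("da", "ga"),
                        stringsAsFactors = FALSE)
  targets <- lapply(seq_len(nrow(combos)), function(i) {
    synthesize_vccv(combos$consonant[i], combos$context[i], timing,
                    seed = derive_seed(seed, i))
  })
  names(targets) <- vapply(targets, `[[`, "", "id")
  targets
}

#' Measure the second-syllable energy onset
#'
#' Locates the closure gap (the last run of exact digital silence of at
#' least 1 ms) and returns the time of the first sample after it.
#'
#' @param target a `target_signal`.
#' @return onset time in seconds.
#' @export
measure_syllable2_onset <- function(target) {
  z <- target$samples == 0
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  min_run <- max(2, round(0.001 * target$sample_rate))
  ok <- r$values & r$lengths >= min_run & ends < length(z)
  if (!any(ok)) stop("no closure gap found")
  i <- max(which(ok))
  ends[i] / target$sample_rate   # first post-gap sample is index ends[i]+1,
                                 # i.e. time ends[i]/fs with 0-based timing
}

#' Generate a white-noise masker
#'
#' I.i.d. Gaussian samples, RMS-normalized, reproducible from
#' `(seed, index)`. The experiment drew a bank of such maskers (one fresh
#' masker per trial); storing `(seed, index)` identifies a masker without
#' materializing the bank.
#'
#' @param n_samples number of samples (> 0).
#' @param seed integer bank seed.
#' @param index masker index within the bank.
#' @return object of class `noise_signal`.
#' @export
generate_noise <- function(n_samples, seed, index = 1L) {
  stopifnot(n_samples > 0)
  samples <- with_seed(derive_seed(seed, index), rnorm(n_samples))
  structure(list(samples = rms_normalize(samples),
                 seed = as.integer(seed), index = as.integer(index)),
            class = "noise_signal")
}

#' Mix a target and a noise masker at a requested SNR
#'
#' Computes `gamma * (target + lambda * noise)` with
#' `lambda = 10^(-snr_db/20)` and `gamma` chosen so the mix has unit RMS.
#' Both inputs must already be RMS-normalized, so the requested broadband
#' SNR holds exactly. An optional raised-cosine noise fade-in can be
#' prepended (a listener-comfort feature); faded samples are excluded from
#' the analysis window via `analysis_start`.
#'
#' @param target a `target_signal` (or unit-RMS numeric vector).
#' @param noise a `noise_signal` (or unit-RMS numeric vector).
#' @param snr_db signal-to-noise ratio in dB.
#' @param fade optional list with `duration` (seconds) for the prepended
#'   noise fade-in; `NULL` (default) for none.
#' @param sample_rate required if both inputs are bare vectors and `fade`
#'   is used.
#' @return object of class `stimulus_mix`.
#' @export
mix_at_snr <- function(target, noise, snr_db, fade = NULL, sample_rate = NULL) {
  t_samp <- if (inherits(target, "target_signal")) target$samples else target
  n_samp <- if (inherits(noise, "noise_signal")) noise$samples else noise
  if (length(t_samp) != length(n_samp)) {
    stop("target and noise must have the same length")
  }
  if (abs(rms(t_samp) - 1) > 1e-6 || abs(rms(n_samp) - 1) > 1e-6) {
    stop("target and noise must be RMS-normalized")
  }
  lambda <- 10^(-snr_db / 20)
  mixed <- t_samp + lambda * n_samp
  gamma <- 1 / rms(mixed)
  samples <- gamma * mixed
  analysis_start <- 1L
  if (!is.null(fade)) {
    fs <- sample_rate %||%
      (if (inherits(target, "target_signal")) target$sample_rate else
         stop("sample_rate needed for fade with bare vectors"))
    n_fade <- round((fade$duration %||% 0.05) * fs)
    if (n_fade > 0) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(n_fade) / n_fade))
      lead <- rev(n_samp[seq_len(min(n_fade, length(n_samp)))])
      lead <- rep_len(lead, n_fade) * ramp * lambda * gamma
      samples <- c(lead, samples)
      analysis_start <- n_fade + 1L
    }
  }
  structure(list(
    samples = samples,
    snr_db = snr_db,
    noise_scale = lambda,
    power_norm = gamma,
    target_ref = if (inherits(target, "target_signal")) target$id else NA_character_,
    noise_ref = if (inherits(noise, "noise_signal")) c(noise$seed, noise$index) else NULL,
    sample_rate = if (inherits(target, "target_signal")) target$sample_rate else sample_rate,
    analysis_start = analysis_start
  ), class = "stimulus_mix")
}
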