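# Shared reduced-scale fixtures, built lazily and cached for the whole
# test run. The reduced configuration (16 kHz, 320 ms targets, 12-channel
# 150-5000 Hz filterbank, 20 ms frames -> 16 x 12 pixel grid) keeps the
# simulations fast; reduced targets carry less discriminable detail than
# the full-scale ones, so reduced-scale observers operate at -6 dB SNR
# where the calibrated 79%-correct level is attainable.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

small_timing <- function() {
  vccv_timing(duration = 0.32, sample_rate = 16000, syllable2_onset = 0.16)
}

small_targets <- function() {
  fx_get("targets", function() default_targets(small_timing(), seed = 1L))
}

small_fb <- function() {
  fx_get("fb", function() {
    make_filterbank(sample_rate = 16000, n_channels = 12, f_lo = 150,
                    f_hi = 5000, time_bin = 0.02)
  })
}

small_cochs <- function() {
  fx_get("cochs", function() {
    lapply(small_targets(), compute_cochleogram, fb = small_fb())
  })
}

small_labels <- function() {
  vapply(small_targets(), `[[`, "", "consonant_label")
}

small_template <- function() {
  fx_get("template", function() {
    ideal_template_from_targets(small_cochs(), small_labels())
  })
}

# calibrated 79%-correct observer at -6 dB on the reduced grid
small_observer <- function() {
  fx_get("observer", function() {
    calibrate_gain(small_template(), small_targets(), small_fb(),
                   snr_db = -6, seed = 2L)
  })
}

# one large fixed-SNR run reused by estimation and acceptance tests
big_table <- function() {
  fx_get("big_table", function() {
    simulate_trials(small_observer(), small_targets(), small_fb(),
                    n_trials = 10000, snr_db = -6, seed = 5L)
  })
}

big_balanced <- function() {
  fx_get("big_balanced", function() balance_trials(big_table(), seed = 1L))
}

# simulate a jittered-template observer sharing the base gain
jitter_observer <- function(jitter_sd, seed) {
  base <- small_observer()
  tpl <- small_template()
  tpl <- tpl + with_seed(seed, matrix(
    rnorm(length(tpl), sd = jitter_sd * sd(tpl)), nrow(tpl)))
  tpl <- tpl / sqrt(sum(tpl^2))
  ref <- fx_get("ref_stimuli", function() {
    reference_stimuli(small_targets(), small_fb(), n_trials = 400,
                      snr_db = -6, seed = 2L)
  })
  dv <- as.numeric(ref$X %*% vectorize(tpl))
  center <- (mean(dv[ref$truth == 1]) + mean(dv[ref$truth == 0])) / 2
  observer_spec(tpl, gain = base$gain, center = center, seed = seed)
}

# observer from an arbitrary unit-norm template, centered on the shared
# reference stimuli and using the base calibrated gain
centered_observer <- function(tpl, seed = 1L) {
  base <- small_observer()
  ref <- fx_get("ref_stimuli", function() {
    reference_stimuli(small_targets(), small_fb(), n_trials = 400,
                      snr_db = -6, seed = 2L)
  })
  dv <- as.numeric(ref$X %*% vectorize(tpl))
  center <- (mean(dv[ref$truth == 1]) + mean(dv[ref$truth == 0])) / 2
  observer_spec(tpl, gain = base$gain, center = center, seed = seed)
}

# random z-map stack helpers for group statistics
null_maps <- function(n_maps, n_time = 12, n_freq = 12, seed = 1) {
  with_seed(seed, lapply(seq_len(n_maps), function(i) {
    matrix(rnorm(n_time * n_freq), n_time, n_freq)
  }))
}
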