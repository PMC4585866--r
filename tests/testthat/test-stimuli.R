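test_that("default synthesis honors the printed duration and onset", {
  tg <- default_targets(seed = 3L)
  expect_length(tg, 4L)
  for (t in tg) {
    expect_equal(length(t$samples), 32640L)   # 0.680 s at 48 kHz
    expect_equal(t$duration, 0.680, tolerance = 1e-12)
    expect_equal(t$syllable2_onset, 0.328, tolerance = 1e-12)
    expect_equal(measure_syllable2_onset(t), 0.328, tolerance = 1e-12)
    expect_equal(rms(t$samples), 1, tolerance = 1e-9)
  }
  # all four targets are equalized in duration and onset
  expect_length(unique(vapply(tg, `[[`, 0, "duration")), 1L)
  expect_length(unique(vapply(tg, `[[`, 0, "syllable2_onset")), 1L)
})

test_that("da and ga differ by their F2/F3 onset separation", {
  da <- synthesize_vccv("da", "l", seed = 1L)
  ga <- synthesize_vccv("ga", "l", seed = 1L)
  sep <- function(t) abs(t$formant_onsets[["F2"]] - t$formant_onsets[["F3"]])
  expect_gt(sep(da), sep(ga))
})

test_that("synthesis is deterministic and rejects invalid inputs", {
  a <- synthesize_vccv("da", "r", small_timing(), seed = 7L)
  b <- synthesize_vccv("da", "r", small_timing(), seed = 7L)
  expect_identical(a$samples, b$samples)
  expect_error(synthesize_vccv("ba", "l"), "arg")
  # formants above Nyquist at a very low sample rate
  low <- vccv_timing(duration = 0.32, sample_rate = 4000,
                     syllable2_onset = 0.16)
  expect_error(synthesize_vccv("da", "l", low), "Nyquist")
})

test_that("noise maskers are reproducible, unit-RMS and spectrally flat", {
  n1 <- generate_noise(32640, seed = 11L, index = 5L)
  n2 <- generate_noise(32640, seed = 11L, index = 5L)
  expect_identical(n1$samples, n2$samples)
  n3 <- generate_noise(32640, seed = 11L, index = 6L)
  expect_false(identical(n1$samples, n3$samples))
  expect_equal(rms(n1$samples), 1, tolerance = 1e-12)
  # empirical autocorrelation at small lags is 0 within sampling error
  ac <- stats::acf(n1$samples, lag.max = 5, plot = FALSE)$acf[-1]
  expect_true(all(abs(ac) < 4 / sqrt(32640)))
  expect_error(generate_noise(0, 1L))
})

test_that("mixing applies the SNR scaling and renormalizes power", {
  t <- rms_normalize(rnorm(2000))
  n <- rms_normalize(rnorm(2000))
  expect_equal(mix_at_snr(t, n, 0)$noise_scale, 1)
  expect_equal(mix_at_snr(t, n, -20)$noise_scale, 10)
  for (snr in c(-20, -11, -3, 0, 6)) {
    m <- mix_at_snr(t, n, snr)
    expect_equal(rms(m$samples), 1, tolerance = 1e-9)
    # post-hoc SNR of the scaled components equals the request exactly
    post <- 20 * log10(rms(m$power_norm * t) /
                         rms(m$power_norm * m$noise_scale * n))
    expect_equal(post, snr, tolerance = 1e-6)
  }
  expect_error(mix_at_snr(t, n[-1], 0), "length")
  expect_error(mix_at_snr(2 * t, n, 0), "normalized")
})

test_that("fade-in prepends noise excluded from the analysis window", {
  tg <- small_targets()[[1]]
  nn <- generate_noise(length(tg$samples), 3L)
  m <- mix_at_snr(tg, nn, -6, fade = list(duration = 0.05))
  n_fade <- round(0.05 * tg$sample_rate)
  expect_equal(m$analysis_start, n_fade + 1L)
  expect_length(m$samples, length(tg$samples) + n_fade)
  # analysis segment is the plain mix
  plain <- mix_at_snr(tg, nn, -6)
  expect_equal(m$samples[m$analysis_start:length(m$samples)],
               plain$samples)
  # fade ramps up from silence
  expect_lt(abs(m$samples[1]), abs(max(m$samples[1:n_fade])))
})

test_that("WAV round trip preserves a target up to PCM quantization", {
  tg <- small_targets()[[2]]
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(tg$samples, tg$sample_rate, path)
  back <- load_wav(path, consonant_label = tg$consonant_label,
                   context_label = tg$context_label,
                   syllable2_onset = tg$syllable2_onset)
  expect_equal(back$sample_rate, tg$sample_rate)
  expect_equal(back$duration, tg$duration)
  expect_equal(back$samples, tg$samples, tolerance = 1e-3)
  expect_gt(cor(back$samples, tg$samples), 0.99999)
})

test_that("degenerate WAV inputs are rejected", {
  # a legitimate PCM file whose samples are all zero
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 200L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(16000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(200L, con, size = 4, endian = "little")
  writeBin(rep(0L, 100), con, size = 2, endian = "little")
  close(con)
  expect_error(load_wav(path), "all-zero")
  expect_error(write_wav(rep(0, 100), 16000, tempfile()), "all-zero")
})
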