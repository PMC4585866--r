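test_that("session initialization follows the session-chaining rule", {
  s1 <- staircase_init()
  expect_equal(s1$snr_db, -11)
  expect_equal(s1$step_db, 2)
  expect_equal(s1$consecutive_correct, 0L)
  s1$snr_db <- -13.4
  s1$consecutive_correct <- 2L
  s1$step_db <- 0.4
  s2 <- staircase_init(s1)
  expect_equal(s2$snr_db, -13.4)     # carries over the final SNR
  expect_equal(s2$step_db, 2)        # step resets each session
  expect_equal(s2$consecutive_correct, 0L)
  expect_equal(s2$session_index, 2L)
})

test_that("the 3-down-1-up update rule moves SNR and decays the step", {
  s <- staircase_init()
  s <- staircase_update(s, FALSE)
  expect_equal(s$snr_db, -9)         # one step up after an error
  expect_equal(s$step_db, 1.8)       # 10% decay at the change
  s <- staircase_init()
  s <- staircase_update(s, TRUE)
  s <- staircase_update(s, TRUE)
  expect_equal(s$snr_db, -11)        # no change before the third correct
  s <- staircase_update(s, TRUE)
  expect_equal(s$snr_db, -13)        # down after three in a row
  expect_equal(s$step_db, 1.8)
  expect_equal(s$consecutive_correct, 0L)
})

test_that("the step reaches its 0.2 dB floor after 22 SNR changes", {
  s <- staircase_init()
  changes <- 0L
  while (s$step_db > 0.2) {
    s <- staircase_update(s, FALSE)  # every error is an SNR change
    changes <- changes + 1L
  }
  expect_equal(changes, 22L)         # smallest n with 2 * 0.9^n <= 0.2
  expect_equal(s$step_db, 0.2)
})

test_that("step stays within [0.2, 2] and SNR only moves at the right trials", {
  s <- staircase_init()
  snr_trace <- s$snr_db
  events <- logical(0)
  set.seed(4)
  for (i in 1:500) {
    correct <- runif(1) < 0.7
    third <- correct && s$consecutive_correct == 2L
    events <- c(events, !correct || third)
    # wide clamp so boundary saturation cannot mask a change
    s <- staircase_update(s, correct, snr_bounds = c(-1e6, 1e6))
    snr_trace <- c(snr_trace, s$snr_db)
    expect_gte(s$step_db, 0.2)
    expect_lte(s$step_db, 2)
  }
  moved <- diff(snr_trace) != 0
  expect_true(all(moved == events))  # changes exactly at errors/3rd-correct
})

test_that("experiment simulation is reproducible from the master seed", {
  obs <- psychometric_observer()
  cfg <- experiment_config(n_sessions = 2, trials_per_session = 200,
                           store_cochleograms = FALSE)
  a <- simulate_experiment(obs, small_targets(), config = cfg, seed = 42L)
  b <- simulate_experiment(obs, small_targets(), config = cfg, seed = 42L)
  expect_identical(a$trials, b$trials)
  expect_equal(nrow(a$trials), 400L)
  # targets drawn uniformly-ish among the four
  expect_length(unique(a$trials$target_id), 4L)
})

test_that("an observer that always answers 'da' is at chance and drives SNR up", {
  obs <- constant_observer(0L)
  cfg <- experiment_config(n_sessions = 1, trials_per_session = 400,
                           store_cochleograms = FALSE)
  log <- simulate_experiment(obs, small_targets(), config = cfg, seed = 8L)
  pc <- mean(log$trials$correct)
  expect_gt(pc, 0.42)                # half the targets are 'da'
  expect_lt(pc, 0.58)
  expect_equal(max(log$trials$snr_db), 10)  # pinned at the safety ceiling
})

test_that("a logistic observer converges near the 79.4% fixed point", {
  obs <- psychometric_observer(threshold = -13, slope = 1)
  cfg <- experiment_config(n_sessions = 6, trials_per_session = 500,
                           store_cochleograms = FALSE)
  log <- simulate_experiment(obs, small_targets(), config = cfg, seed = 21L)
  pc <- mean(log$trials$correct[501:3000])
  expect_equal(pc, 0.5^(1 / 3), tolerance = 0.04)
})
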