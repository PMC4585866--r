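# 3-down-1-up adaptive SNR staircase and whole-experiment simulation.
#
# The transformed up-down rule (lower SNR after three consecutive correct
# responses, raise it after each error) converges on the SNR at which
# P(correct) = 0.5^(1/3) = 79.4%, so task difficulty is equalized across
# listeners. The step starts at 2 dB each session and shrinks by 10% at
# every SNR change down to a 0.2 dB floor.

#' Initialize a staircase session
#'
#' The first session starts at -11 dB SNR; later sessions start at the
#' final SNR of the previous session. The step size is reset to 2 dB and
#' the consecutive-correct counter to zero at each session start.
#'
#' @param previous final `staircase_state` of the previous session, or
#'   `NULL` for the first session.
#' @param initial_snr starting SNR (dB) for the first session.
#' @param initial_step starting step size (dB).
#' @return object of class `staircase_state`.
#' @export
staircase_init <- function(previous = NULL, initial_snr = -11,
                           initial_step = 2) {
  structure(list(
    snr_db = if (is.null(previous)) initial_snr else previous$snr_db,
    step_db = initial_step,
    consecutive_correct = 0L,
    trial_index = 0L,
    session_index = if (is.null(previous)) 1L else previous$session_index + 1L
  ), class = "staircase_state")
}

#' Advance the staircase by one trial
#'
#' An incorrect response raises the SNR by one step; a third consecutive
#' correct response lowers it by one step. Every SNR change multiplies the
#' step by `decay` (floored at `step_floor`). SNR is clamped to
#' `snr_bounds`, a safety range never reached by realistic observers.
#'
#' @param state current `staircase_state`.
#' @param correct logical; was the response correct?
#' @param decay multiplicative step decay applied at each SNR change.
#' @param step_floor minimum step size (dB).
#' @param snr_bounds length-2 numeric, SNR clamp (dB).
#' @return updated `staircase_state`.
#' @export
staircase_update <- function(state, correct, decay = 0.9, step_floor = 0.2,
                             snr_bounds = c(-40, 10)) {
  state$trial_index <- state$trial_index + 1L
  if (!correct) {
    state$snr_db <- min(snr_bounds[2], state$snr_db + state$step_db)
    state$step_db <- max(step_floor, state$step_db * decay)
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct == 3L) {
      state$snr_db <- max(snr_bounds[1], state$snr_db - state$step_db)
      state$step_db <- max(step_floor, state$step_db * decay)
      state$consecutive_correct <- 0L
    }
  }
  state
}

#' Default experiment configuration
#'
#' Defaults are the study conditions: 20 sessions of 500 trials, initial
#' SNR -11 dB, 2 dB initial step decaying by 10% per change to a 0.2 dB
#' floor.
#'
#' @param n_sessions number of sessions.
#' @param trials_per_session trials per session.
#' @param initial_snr first-session starting SNR (dB).
#' @param initial_step session-start step size (dB).
#' @param step_decay multiplicative decay per SNR change.
#' @param step_floor minimum step (dB).
#' @param snr_bounds SNR safety clamp (dB).
#' @param fade optional fade-in passed to [mix_at_snr()].
#' @param store_cochleograms logical; keep per-trial pixel vectors (needed
#'   for template estimation, memory-heavy for long runs).
#' @return named list.
#' @export
experiment_config <- function(n_sessions = 20, trials_per_session = 500,
                              initial_snr = -11, initial_step = 2,
                              step_decay = 0.9, step_floor = 0.2,
                              snr_bounds = c(-40, 10), fade = NULL,
                              store_cochleograms = TRUE) {
  list(n_sessions = n_sessions, trials_per_session = trials_per_session,
       initial_snr = initial_snr, initial_step = initial_step,
       step_decay = step_decay, step_floor = step_floor,
       snr_bounds = snr_bounds, fade = fade,
       store_cochleograms = store_cochleograms)
}

#' Simulate a full adaptive experiment
#'
#' Per trial: a target is drawn uniformly among the supplied targets, a
#' fresh noise masker is generated, target and noise are mixed at the
#' current staircase SNR, the observer is queried, and the staircase is
#' updated from the correctness of the response. Audio and cochleograms
#' are computed lazily: observers that decide from the trial SNR alone
#' (class `psychometric_observer`) skip waveform synthesis entirely.
#' A single staircase spans all targets, and every source of randomness
#' derives from `seed`.
#'
#' @param observer an observer (see [observer_spec()],
#'   [psychometric_observer()]).
#' @param targets list of `target_signal`s (the response classes are their
#'   `consonant_label`s).
#' @param fb a `filterbank` (required for cochleogram-based observers).
#' @param config list from [experiment_config()].
#' @param seed master seed.
#' @return object of class `experiment_log`: list with `trials`
#'   (data.frame: session, trial, target_id, noise_index, snr_db, step_db,
#'   response, correct), optional `X` pixel matrix, `config`, `seed`,
#'   `grid`.
#' @export
simulate_experiment <- function(observer, targets, fb = NULL,
                                config = experiment_config(), seed = 1L) {
  needs_audio <- !inherits(observer, "psychometric_observer")
  if (needs_audio && is.null(fb)) {
    stop("a filterbank is required for cochleogram-based observers")
  }
  n_total <- config$n_sessions * config$trials_per_session
  labels <- vapply(targets, `[[`, "", "consonant_label")
  n_samples <- if (needs_audio) length(targets[[1]]$samples) else 0L
  grid <- NULL
  X <- NULL

  session <- integer(n_total); trial <- integer(n_total)
  target_id <- character(n_total); noise_index <- integer(n_total)
  snr_db <- numeric(n_total); step_db <- numeric(n_total)
  response <- integer(n_total); correct <- logical(n_total)

  with_seed(derive_seed(seed, 1L), {
    state <- NULL
    i <- 0L
    for (s in seq_len(config$n_sessions)) {
      state <- staircase_init(state, config$initial_snr, config$initial_step)
      for (k in seq_len(config$trials_per_session)) {
        i <- i + 1L
        ti <- sample.int(length(targets), 1L)
        snr_db[i] <- state$snr_db
        step_db[i] <- state$step_db
        session[i] <- s
        trial[i] <- k
        target_id[i] <- targets[[ti]]$id
        noise_index[i] <- i
        truth <- if (labels[ti] == "ga") 1L else 0L
        if (needs_audio) {
          noise <- generate_noise(n_samples, derive_seed(seed, 2L), index = i)
          mix <- mix_at_snr(targets[[ti]], noise, state$snr_db,
                            fade = config$fade)
          coch <- compute_cochleogram(mix, fb)
          if (is.null(grid)) {
            grid <- dim(coch$values)
            if (config$store_cochleograms) {
              X <- matrix(NA_real_, n_total, prod(grid))
            }
          }
          if (config$store_cochleograms) X[i, ] <- vectorize(coch)
          response[i] <- respond(observer, coch)
        } else {
          response[i] <- respond(observer, snr_db = state$snr_db,
                                 truth = truth)
        }
        correct[i] <- response[i] == truth
        state <- staircase_update(state, correct[i], config$step_decay,
                                  config$step_floor, config$snr_bounds)
      }
    }
  })

  structure(list(
    trials = data.frame(session = session, trial = trial,
                        target_id = target_id, noise_index = noise_index,
                        snr_db = snr_db, step_db = step_db,
                        response = response, correct = correct,
                        stringsAsFactors = FALSE),
    X = X, grid = grid, config = config, seed = as.integer(seed),
    noise_seed = derive_seed(seed, 2L),
    observer_class = class(observer)[1]
  ), class = "experiment_log")
}

#' Simulate trials at fixed SNR
#'
#' Convenience generator for estimation studies: draws targets and fresh
#' noise, mixes at a fixed SNR, computes cochleograms, and queries a
#' cochleogram-based observer — without the adaptive staircase.
#'
#' @inheritParams simulate_experiment
#' @param n_trials number of trials.
#' @param snr_db fixed SNR in dB.
#' @return a `trial_table` (see [trial_table()]).
#' @export
simulate_trials <- function(observer, targets, fb, n_trials, snr_db,
                            seed = 1L) {
  labels <- vapply(targets, `[[`, "", "consonant_label")
  n_samples <- length(targets[[1]]$samples)
  X <- NULL
  response <- integer(n_trials); correct <- logical(n_trials)
  target_id <- character(n_trials)
  grid <- NULL
  with_seed(derive_seed(seed, 1L), {
    for (i in seq_len(n_trials)) {
      ti <- sample.int(length(targets), 1L)
      noise <- generate_noise(n_samples, derive_seed(seed, 2L), index = i)
      mix <- mix_at_snr(targets[[ti]], noise, snr_db)
      coch <- compute_cochleogram(mix, fb)
      if (is.null(X)) {
        grid <- dim(coch$values)
        X <- matrix(NA_real_, n_trials, prod(grid))
      }
      X[i, ] <- vectorize(coch)
      truth <- if (labels[ti] == "ga") 1L else 0L
      response[i] <- respond(observer, coch)
      correct[i] <- response[i] == truth
      target_id[i] <- targets[[ti]]$id
    }
  })
  trial_table(X = X, response = response, correct = correct,
              target_id = target_id, snr_db = rep(snr_db, n_trials),
              session = rep(1L, n_trials), grid = grid)
}
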