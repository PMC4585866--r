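# Simulated observers.
#
# The linear observer is the decision model underlying the classification
# image itself: the response probability is an inverse-logit of the dot
# product between the stimulus cochleogram and an internal template, plus
# a bias. Simulating such observers gives the estimation machinery a known
# ground truth for parameter-recovery checks. Internal noise is absorbed
# into the logistic through the gain parameter (higher gain = less
# internal noise), so the generating model and the fitted model share one
# likelihood family.

#' Specify a linear-template observer
#'
#' The response probability is
#' `plogis(gain * (<S, template> - center) + bias)`. `center` anchors the
#' decision variable at the category boundary: cochleograms are
#' non-negative energy maps, so the raw dot product carries a large
#' class-independent offset that a listener's criterion sits on top of;
#' `center` is that offset (see [calibrate_gain()]), and `bias` is the
#' listener's bias proper toward 'ga'.
#'
#' @param template ground-truth weight map (matrix on the cochleogram grid,
#'   or pixel vector).
#' @param bias scalar bias toward responding 'ga'.
#' @param gain positive scalar scaling the decision variable.
#' @param center decision-variable centering constant.
#' @param seed optional integer recorded with the spec.
#' @return object of class `linear_observer`.
#' @export
observer_spec <- function(template, bias = 0, gain = 1, center = 0,
                          seed = NULL) {
  stopifnot(is.numeric(gain), length(gain) == 1, gain > 0)
  structure(list(template = template, bias = bias, gain = gain,
                 center = center, seed = seed),
            class = c("linear_observer", "observer"))
}

#' Specify a psychometric (SNR-driven) observer
#'
#' Answers correctly with probability
#' `guess + (1 - guess) * plogis(slope * (snr - threshold))`: a logistic
#' psychometric function with a guessing floor (a two-choice task cannot
#' fall below 50% correct). `threshold` is the SNR of the psychometric
#' midpoint.
#'
#' @param threshold SNR (dB) at the midpoint of the rise.
#' @param slope logistic slope per dB.
#' @param guess guessing floor (0.5 for a two-alternative task).
#' @return object of class `psychometric_observer`.
#' @export
psychometric_observer <- function(threshold = -13, slope = 1, guess = 0.5) {
  structure(list(threshold = threshold, slope = slope, guess = guess),
            class = c("psychometric_observer", "observer"))
}

#' Specify a constant-response observer
#'
#' Always answers the same label; useful as a degenerate control.
#'
#' @param response 0 ('da') or 1 ('ga').
#' @return object of class `psychometric_observer` variant.
#' @export
constant_observer <- function(response = 0L) {
  structure(list(response = as.integer(response)),
            class = c("constant_observer", "psychometric_observer",
                      "observer"))
}

#' Query an observer for a response
#'
#' @param observer an observer object.
#' @param ... stimulus information: cochleogram (linear observers) or
#'   `snr_db` and `truth` (psychometric observers).
#' @return integer response, 0 ('da') or 1 ('ga').
#' @export
respond <- function(observer, ...) UseMethod("respond")

#' @rdname respond
#' @param cochleogram a `cochleogram` or pixel vector (linear observers).
#' @export
respond.linear_observer <- function(observer, cochleogram, ...) {
  stats::rbinom(1L, 1L, response_probability(observer, cochleogram))
}

#' @rdname respond
#' @param snr_db trial SNR in dB.
#' @param truth correct response label (0/1).
#' @export
respond.psychometric_observer <- function(observer, snr_db, truth, ...) {
  p_correct <- observer$guess + (1 - observer$guess) *
    stats::plogis(observer$slope * (snr_db - observer$threshold))
  if (stats::rbinom(1L, 1L, p_correct) == 1L) truth else 1L - truth
}

#' @rdname respond
#' @export
respond.constant_observer <- function(observer, ...) observer$response

#' Decision-variable probability of a linear observer
#'
#' Deterministic part of [respond.linear_observer()]: the probability of
#' answering 'ga' for a given cochleogram.
#'
#' @param observer a `linear_observer`.
#' @param cochleogram a `cochleogram` or pixel vector.
#' @return probability in (0, 1).
#' @export
response_probability <- function(observer, cochleogram) {
  s <- if (inherits(cochleogram, "cochleogram")) cochleogram$values else cochleogram
  if (length(s) != length(observer$template)) {
    stop("cochleogram does not match the observer's template grid")
  }
  tpl <- observer$template
  # a bare vector stimulus is a vectorize()-ordered pixel vector
  if (!is.matrix(s) && is.matrix(tpl)) tpl <- vectorize(tpl)
  dv <- sum(as.vector(s) * as.vector(tpl))
  stats::plogis(observer$gain * (dv - (observer$center %||% 0)) +
                  observer$bias)
}

#' Ideal template from the target cochleograms
#'
#' Mean 'ga'-class cochleogram minus mean 'da'-class cochleogram,
#' normalized to unit Frobenius norm. This is the discriminant a noiseless
#' matched-template listener would use; it concentrates on the
#' formant-transition onsets where the classes differ.
#'
#' @param cochleograms list of `cochleogram`s (or matrices).
#' @param labels character vector of `"da"`/`"ga"` class labels, one per
#'   cochleogram.
#' @return template matrix with unit Frobenius norm.
#' @export
ideal_template_from_targets <- function(cochleograms, labels) {
  stopifnot(length(cochleograms) == length(labels))
  mats <- lapply(cochleograms, function(cc) {
    if (inherits(cc, "cochleogram")) cc$values else cc
  })
  ga <- mats[labels == "ga"]
  da <- mats[labels == "da"]
  if (length(ga) == 0 || length(da) == 0) {
    stop("need at least one cochleogram per class")
  }
  tpl <- Reduce(`+`, ga) / length(ga) - Reduce(`+`, da) / length(da)
  tpl / sqrt(sum(tpl^2))
}

#' Reference stimulus set for observer calibration
#'
#' Simulates `n_trials` noisy stimuli at a fixed SNR and returns their
#' cochleogram pixel matrix and true class labels, for use by
#' [calibrate_gain()].
#'
#' @param targets list of `target_signal`s.
#' @param fb a `filterbank`.
#' @param n_trials number of stimuli.
#' @param snr_db SNR in dB.
#' @param seed integer seed.
#' @return list with `X` (`n_trials x p` matrix) and `truth` (0/1).
#' @export
reference_stimuli <- function(targets, fb, n_trials = 400, snr_db = -12,
                              seed = 1L) {
  labels <- vapply(targets, `[[`, "", "consonant_label")
  n_samples <- length(targets[[1]]$samples)
  X <- NULL
  truth <- integer(n_trials)
  with_seed(derive_seed(seed, 41L), {
    for (i in seq_len(n_trials)) {
      ti <- sample.int(length(targets), 1L)
      noise <- generate_noise(n_samples, derive_seed(seed, 42L), index = i)
      mix <- mix_at_snr(targets[[ti]], noise, snr_db)
      v <- vectorize(compute_cochleogram(mix, fb))
      if (is.null(X)) X <- matrix(NA_real_, n_trials, length(v))
      X[i, ] <- v
      truth[i] <- if (labels[ti] == "ga") 1L else 0L
    }
  })
  list(X = X, truth = truth, snr_db = snr_db)
}

#' Calibrate a linear observer against a target accuracy
#'
#' Simulates a reference set of noisy stimuli at `snr_db`, sets the
#' decision-variable `center` to the midpoint of the class-conditional
#' mean dot products, then bisects on log-gain so that the observer's
#' expected proportion correct on the reference set matches
#' `target_accuracy`. The expectation is computed analytically from the
#' response probabilities (no response sampling), so the bisection target
#' is monotone and deterministic. Used to place simulated listeners at a
#' realistic performance level: calibrating to 79% near -12 dB makes the
#' staircase settle near -12 dB.
#'
#' @param template template matrix.
#' @param targets list of `target_signal`s.
#' @param fb a `filterbank`.
#' @param snr_db reference SNR (dB).
#' @param target_accuracy desired expected proportion correct at `snr_db`.
#' @param n_trials reference stimuli used for calibration.
#' @param bias observer bias.
#' @param seed integer seed.
#' @param gain_range log10 search range for the gain.
#' @param ref optional precomputed [reference_stimuli()] set (avoids
#'   re-simulating when calibrating many observers).
#' @return a calibrated `linear_observer`, with attributes
#'   `expected_accuracy` (at the calibrated gain) and `max_accuracy` (the
#'   deterministic, infinite-gain ceiling on the reference set). If the
#'   ceiling is below `target_accuracy` the external noise alone limits
#'   performance; a warning is issued and the upper-range gain returned.
#' @export
calibrate_gain <- function(template, targets, fb, snr_db = -12,
                           target_accuracy = 0.79, n_trials = 400,
                           bias = 0, seed = 1L, gain_range = c(-2, 5),
                           ref = NULL) {
  if (is.null(ref)) {
    ref <- reference_stimuli(targets, fb, n_trials, snr_db, seed)
  }
  tpl <- if (is.matrix(template)) vectorize(template) else template
  dv <- as.numeric(ref$X %*% tpl)
  truth <- ref$truth
  center <- (mean(dv[truth == 1]) + mean(dv[truth == 0])) / 2
  exp_acc <- function(gain) {
    p_ga <- stats::plogis(gain * (dv - center) + bias)
    mean(ifelse(truth == 1L, p_ga, 1 - p_ga))
  }
  max_acc <- mean(ifelse(truth == 1L, dv > center, dv < center))
  lo <- gain_range[1]; hi <- gain_range[2]
  if (exp_acc(10^hi) < target_accuracy) {
    warning("external noise limits accuracy to ",
            round(max_acc, 3), " at ", snr_db,
            " dB; target accuracy unreachable, returning maximum gain")
    lo <- hi
  }
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    if (exp_acc(10^mid) < target_accuracy) lo <- mid else hi <- mid
  }
  gain <- 10^((lo + hi) / 2)
  obs <- observer_spec(template, bias = bias, gain = gain, center = center,
                       seed = seed)
  attr(obs, "expected_accuracy") <- exp_acc(gain)
  attr(obs, "max_accuracy") <- max_acc
  obs
}
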