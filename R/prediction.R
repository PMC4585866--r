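# Auto- and cross-prediction analysis.
#
# How well does a listener's fitted template predict held-out responses —
# their own (auto-prediction, 10-fold cross-validation) or another
# listener's (cross-prediction)? The gap between the two quantifies the
# specificity of a listener's strategy. Goodness of fit is reported as
# deviance (-2 log-likelihood; lower is better), with prediction accuracy
# alongside for interpretability.

#' Binomial deviance of predicted probabilities
#'
#' `-2 * sum(r*log(p) + (1-r)*log(1-p))`, with probabilities clipped away
#' from 0 and 1.
#'
#' @param probabilities predicted probabilities of responding 'ga'.
#' @param responses observed 0/1 responses.
#' @return scalar deviance (>= 0).
#' @export
deviance_score <- function(probabilities, responses) {
  if (length(probabilities) != length(responses)) {
    stop("probabilities and responses must have equal length")
  }
  p <- clip_prob(probabilities)
  r <- responses
  -2 * sum(r * log(p) + (1 - r) * log(1 - p))
}

#' Prediction accuracy of predicted probabilities
#'
#' Fraction of trials on which the predicted-probability side of 0.5
#' matches the response. Ties at exactly 0.5 count as incorrect
#' (conservative).
#'
#' @inheritParams deviance_score
#' @return accuracy in \[0, 1\].
#' @export
accuracy_score <- function(probabilities, responses) {
  if (length(probabilities) != length(responses)) {
    stop("probabilities and responses must have equal length")
  }
  mean((probabilities > 0.5 & responses == 1) |
         (probabilities < 0.5 & responses == 0))
}

# Shared machinery: fit fold models on train_table, score fold partitions
# of test_table. With train == test (and the same fold seed) this is
# exactly 10-fold cross-validated auto-prediction.
fold_prediction <- function(train_table, test_table, penalty_weight,
                            n_folds = 10, K = NULL, seed = 1L) {
  if (train_table$grid[1] != test_table$grid[1] ||
      train_table$grid[2] != test_table$grid[2]) {
    stop("train and test tables use different pixel grids")
  }
  if (is.null(K)) {
    K <- laplacian_penalty(train_table$grid[1], train_table$grid[2])
  }
  train_folds <- make_folds(train_table$response, n_folds, seed)
  test_folds <- make_folds(test_table$response, n_folds, seed)
  dev <- numeric(n_folds); acc <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    fit <- fit_aci(table_subset(train_table, train_folds != k),
                   penalty_weight, K = K)
    held <- table_subset(test_table, test_folds == k)
    pr <- predict(fit, held)
    dev[k] <- deviance_score(pr, held$response)
    acc[k] <- accuracy_score(pr, held$response)
  }
  list(deviance = mean(dev), accuracy = mean(acc))
}

#' Auto-prediction by 10-fold cross-validation
#'
#' The listener's balanced data are split into `n_folds` stratified
#' subsets; a model fitted on each training set is scored on the held-out
#' subset, and the fold deviances/accuracies are averaged.
#'
#' @param table balanced `trial_table`.
#' @param penalty_weight shared smoothness penalty.
#' @param n_folds number of folds.
#' @param K optional penalty matrix.
#' @param seed fold seed.
#' @return list with `deviance` and `accuracy`.
#' @export
auto_prediction <- function(table, penalty_weight, n_folds = 10, K = NULL,
                            seed = 1L) {
  fold_prediction(table, table, penalty_weight, n_folds, K, seed)
}

#' Cross-prediction between two listeners
#'
#' Same protocol as [auto_prediction()] except that the test partitions
#' come from a different listener: fold models fitted on the training
#' listener's data are scored on matched partitions of the test
#' listener's balanced data, keeping deviances on the same scale as
#' auto-prediction.
#'
#' @param train_table balanced `trial_table` the models are fitted on.
#' @param test_table balanced `trial_table` that is scored.
#' @inheritParams auto_prediction
#' @return list with `deviance` and `accuracy`.
#' @export
cross_prediction <- function(train_table, test_table, penalty_weight,
                             n_folds = 10, K = NULL, seed = 1L) {
  fold_prediction(train_table, test_table, penalty_weight, n_folds, K, seed)
}

#' Full train-by-test prediction matrix
#'
#' Deviance and accuracy for every (train listener, test listener) pair;
#' the diagonal holds the 10-fold auto-predictions.
#'
#' @param tables named list of balanced `trial_table`s (one per listener).
#' @inheritParams auto_prediction
#' @return object of class `prediction_matrix`: list with `deviance` and
#'   `accuracy` (`N x N` matrices, rows = train listener, columns = test
#'   listener), `listeners`, `penalty_weight`, `seed`.
#' @export
prediction_matrix <- function(tables, penalty_weight, n_folds = 10,
                              seed = 1L) {
  n <- length(tables)
  ids <- names(tables) %||% paste0("L", seq_len(n))
  K <- laplacian_penalty(tables[[1]]$grid[1], tables[[1]]$grid[2])
  dev <- matrix(NA_real_, n, n, dimnames = list(train = ids, test = ids))
  acc <- dev
  # fit each listener's fold models once, then score on every test listener
  for (i in seq_len(n)) {
    train_folds <- make_folds(tables[[i]]$response, n_folds,
                              derive_seed(seed, i))
    fits <- lapply(seq_len(n_folds), function(k) {
      fit_aci(table_subset(tables[[i]], train_folds != k), penalty_weight,
              K = K)
    })
    for (j in seq_len(n)) {
      test_folds <- make_folds(tables[[j]]$response, n_folds,
                               derive_seed(seed, j))
      dv <- numeric(n_folds); ac <- numeric(n_folds)
      for (k in seq_len(n_folds)) {
        held <- table_subset(tables[[j]], test_folds == k)
        pr <- predict(fits[[k]], held)
        dv[k] <- deviance_score(pr, held$response)
        ac[k] <- accuracy_score(pr, held$response)
      }
      dev[i, j] <- mean(dv)
      acc[i, j] <- mean(ac)
    }
  }
  structure(list(deviance = dev, accuracy = acc, listeners = ids,
                 penalty_weight = penalty_weight, seed = as.integer(seed)),
            class = "prediction_matrix")
}

#' Specificity of a listener's strategy
#'
#' Auto-prediction deviance minus the mean cross-prediction deviance of
#' the listener's data under the other listeners' models. Lower deviance
#' means a better fit, so a listener whose own model predicts their data
#' best gets a negative specificity.
#'
#' @param pm a `prediction_matrix`.
#' @param listener listener index or id; omit for all listeners.
#' @return named numeric vector of specificity values.
#' @export
specificity_score <- function(pm, listener = NULL) {
  n <- length(pm$listeners)
  if (n < 2) stop("specificity requires at least two listeners")
  idx <- if (is.null(listener)) seq_len(n) else {
    if (is.character(listener)) match(listener, pm$listeners) else listener
  }
  out <- vapply(idx, function(i) {
    pm$deviance[i, i] - mean(pm$deviance[-i, i])
  }, 0)
  names(out) <- pm$listeners[idx]
  out
}

#' Signal-detection metrics of a trial table
#'
#' Treating 'ga' as the signal: hit rate = P(respond 'ga' | 'ga' target),
#' false-alarm rate = P(respond 'ga' | 'da' target). Extreme rates are
#' corrected by the 1/(2N) rule before taking normal quantiles.
#' `d' = qnorm(hit) - qnorm(fa)`; `criterion = -(qnorm(hit)+qnorm(fa))/2`.
#'
#' @param table a `trial_table` containing both target classes, or a list
#'   with `response` and `target_id`/`truth`.
#' @return object of class `sdt_metrics`: list with `d_prime`,
#'   `criterion`, `hit_rate`, `fa_rate`.
#' @export
sdt_metrics <- function(table) {
  truth <- if (!is.null(table$target_id) && !all(is.na(table$target_id))) {
    ifelse(grepl("ga$", table$target_id), 1L, 0L)
  } else if (!is.null(table$truth)) {
    table$truth
  } else {
    stop("table must identify the target class of each trial")
  }
  r <- table$response
  n_sig <- sum(truth == 1); n_noise <- sum(truth == 0)
  if (n_sig == 0 || n_noise == 0) {
    stop("both target classes must be present")
  }
  correct_rate <- function(x, n) {
    if (x == 0) 1 / (2 * n) else if (x == 1) 1 - 1 / (2 * n) else x
  }
  hit <- correct_rate(mean(r[truth == 1]), n_sig)
  fa <- correct_rate(mean(r[truth == 0]), n_noise)
  structure(list(
    d_prime = stats::qnorm(hit) - stats::qnorm(fa),
    criterion = -(stats::qnorm(hit) + stats::qnorm(fa)) / 2,
    hit_rate = hit, fa_rate = fa
  ), class = "sdt_metrics")
}
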