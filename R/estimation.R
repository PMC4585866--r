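# Classification-image estimation: maximum a posteriori penalized
# logistic regression of the trial-by-trial responses on stimulus
# cochleograms, with a 2-D smoothness prior on the time-frequency grid.
#
# Model: P(r_i = 'ga') = logit^-1( <S_i, beta> + c ), with penalty
# (lambda/2) * beta' K beta, K = D'D for D the discrete 2-D Laplacian
# (Neumann boundaries) plus a vanishing ridge that removes the Laplacian's
# constant nullspace (constant offsets belong in the bias c). The bias is
# unpenalized. Fitting is Newton (penalized IRLS) with Jacobi-
# preconditioned conjugate-gradient inner solves and step halving.

#' Construct a trial table
#'
#' The design table for estimation: one row per trial with the stimulus
#' pixel vector, the binary response (0 'da', 1 'ga'), and bookkeeping.
#'
#' @param X `n x p` matrix of pixel vectors (rows are trials).
#' @param response integer 0/1 responses.
#' @param correct logical correctness per trial.
#' @param target_id character target identifiers.
#' @param snr_db per-trial SNR (dB).
#' @param session per-trial session index.
#' @param grid `c(n_time, n_freq)` of the pixel grid.
#' @param time_bin,center_freqs optional grid metadata (seconds, Hz).
#' @param balanced logical; has correct/error balancing been applied?
#' @return object of class `trial_table`.
#' @export
trial_table <- function(X, response, correct, target_id = NULL,
                        snr_db = NULL, session = NULL, grid = NULL,
                        time_bin = NULL, center_freqs = NULL,
                        balanced = FALSE) {
  n <- length(response)
  stopifnot(is.matrix(X), nrow(X) == n, length(correct) == n,
            all(response %in% 0:1))
  structure(list(
    X = X, response = as.integer(response), correct = as.logical(correct),
    target_id = target_id %||% rep(NA_character_, n),
    snr_db = snr_db %||% rep(NA_real_, n),
    session = session %||% rep(1L, n),
    grid = grid %||% c(1L, ncol(X)),
    time_bin = time_bin, center_freqs = center_freqs,
    balanced = balanced
  ), class = "trial_table")
}

#' Build a trial table from an experiment log
#'
#' @param log an `experiment_log` with stored cochleograms.
#' @param fb optional `filterbank` supplying grid metadata.
#' @return a `trial_table`.
#' @export
log_to_table <- function(log, fb = NULL) {
  if (is.null(log$X)) {
    stop("experiment log has no stored cochleograms ",
         "(run with store_cochleograms = TRUE)")
  }
  trial_table(X = log$X, response = log$trials$response,
              correct = log$trials$correct,
              target_id = log$trials$target_id,
              snr_db = log$trials$snr_db, session = log$trials$session,
              grid = log$grid,
              time_bin = fb$time_bin, center_freqs = fb$center_freqs)
}

#' Subset a trial table by row
#'
#' @param table a `trial_table`.
#' @param idx integer or logical row index.
#' @return a `trial_table` with the selected trials.
#' @export
subset_trials <- function(table, idx) table_subset(table, idx)

# subset rows of a trial table
table_subset <- function(table, idx) {
  out <- table
  out$X <- table$X[idx, , drop = FALSE]
  for (f in c("response", "correct", "target_id", "snr_db", "session")) {
    out[[f]] <- table[[f]][idx]
  }
  out
}

#' Balance correct and incorrect trials
#'
#' The staircase holds performance near 79% correct, so correct trials
#' outnumber errors roughly 4:1; the penalized GLM is sensitive to this
#' imbalance. Balancing discards randomly chosen correct trials until the
#' two counts are equal (trial order otherwise preserved).
#'
#' @param table a `trial_table` with at least one error trial.
#' @param seed integer seed for the random discards.
#' @return balanced `trial_table`.
#' @export
balance_trials <- function(table, seed = 1L) {
  n_err <- sum(!table$correct)
  n_cor <- sum(table$correct)
  if (n_err == 0) {
    stop("cannot balance a table with zero error trials: ",
         "every trial was answered correctly")
  }
  if (n_cor <= n_err) {
    table$balanced <- TRUE
    return(table)
  }
  cor_idx <- which(table$correct)
  keep_cor <- with_seed(derive_seed(seed, 11L),
                        sort(sample(cor_idx, n_err)))
  idx <- sort(c(which(!table$correct), keep_cor))
  out <- table_subset(table, idx)
  out$balanced <- TRUE
  out
}

#' Smoothness penalty matrix for a time-frequency grid
#'
#' `K = D'D` with `D` the discrete 2-D Laplacian on the `n_time x n_freq`
#' grid with reflecting (Neumann) boundaries, plus `ridge * I` to remove
#' the Laplacian's constant nullspace. Pixel ordering matches
#' [vectorize()] (time-major).
#'
#' @param n_time,n_freq grid dimensions.
#' @param ridge small ridge added to the diagonal.
#' @return sparse symmetric `p x p` Matrix.
#' @export
laplacian_penalty <- function(n_time, n_freq, ridge = 1e-6) {
  p <- n_time * n_freq
  pix <- function(t, f) (t - 1) * n_freq + f
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (t in seq_len(n_time)) {
    for (f in seq_len(n_freq)) {
      i <- pix(t, f)
      nb <- c(if (t > 1) pix(t - 1, f), if (t < n_time) pix(t + 1, f),
              if (f > 1) pix(t, f - 1), if (f < n_freq) pix(t, f + 1))
      ii <- c(ii, i, rep(i, length(nb)))
      jj <- c(jj, i, nb)
      vv <- c(vv, -length(nb), rep(1, length(nb)))
    }
  }
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(p, p))
  Matrix::crossprod(D) + ridge * Matrix::Diagonal(p)
}

# Jacobi-preconditioned conjugate gradient for SPD systems given as a
# matvec closure.
cg_solve <- function(matvec, b, diag_precond, tol = 1e-10, maxit = 500) {
  x <- numeric(length(b))
  r <- b
  z <- r / diag_precond
  p <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b^2))
  if (b_norm == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- matvec(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * b_norm) break
    z <- r / diag_precond
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

#' Fit a classification image by penalized logistic regression
#'
#' Maximum a posteriori estimate of the template `beta` and bias `c`
#' minimizing the penalized negative log-likelihood
#' `-sum(r*log(p) + (1-r)*log(1-p)) + (lambda/2) * beta' K beta`.
#' Newton iterations with conjugate-gradient inner solves; step halving
#' guarantees a monotonically decreasing objective; convergence is
#' declared when the gradient norm falls below `tol * (1 + |objective|)`.
#'
#' @param table a `trial_table` (a warning is issued if unbalanced).
#' @param penalty_weight smoothness penalty `lambda >= 0`.
#' @param K penalty matrix; defaults to [laplacian_penalty()] on the
#'   table's grid.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return object of class `aci_model`: `template` (matrix on the grid),
#'   `bias`, `penalty_weight`, `converged`, `final_objective`,
#'   `n_trials_used`, `n_iter`, plus grid metadata.
#' @export
fit_aci <- function(table, penalty_weight, K = NULL, tol = 1e-6,
                    max_iter = 200) {
  stopifnot(penalty_weight >= 0)
  if (!isTRUE(table$balanced)) {
    warning("fitting an unbalanced trial table; estimates may be distorted")
  }
  y <- table$response
  if (length(unique(y)) < 2) {
    stop("degenerate responses: all trials share the same response")
  }
  n_time <- table$grid[1]; n_freq <- table$grid[2]
  p <- n_time * n_freq
  if (is.null(K)) K <- laplacian_penalty(n_time, n_freq)
  # center predictors; the bias is mapped back to the raw scale afterwards
  m <- colMeans(table$X)
  X <- sweep(table$X, 2, m)
  n <- nrow(X)
  lam <- penalty_weight
  diagK <- Matrix::diag(K)

  beta <- numeric(p); cc <- stats::qlogis(clip_prob(mean(y)))
  eta <- as.numeric(X %*% beta) + cc
  obj_of <- function(eta, beta) {
    pr <- clip_prob(stats::plogis(eta))
    -sum(y * log(pr) + (1 - y) * log(1 - pr)) +
      (lam / 2) * sum(beta * as.numeric(K %*% beta))
  }
  obj <- obj_of(eta, beta)
  obj_trace <- obj
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-10)
    g_beta <- as.numeric(crossprod(X, pr - y)) + lam * as.numeric(K %*% beta)
    g_c <- sum(pr - y)
    g <- c(g_beta, g_c)
    if (sqrt(sum(g^2)) <= tol * (1 + abs(obj))) {
      converged <- TRUE
      break
    }
    diag_h <- c(as.numeric(crossprod(X^2, w)) + lam * diagK, sum(w))
    matvec <- function(v) {
      vb <- v[1:p]; vc <- v[p + 1]
      Xv <- as.numeric(X %*% vb) + vc
      wXv <- w * Xv
      c(as.numeric(crossprod(X, wXv)) + lam * as.numeric(K %*% vb),
        sum(wXv))
    }
    d <- cg_solve(matvec, -g, diag_h)
    step <- 1
    repeat {
      beta_new <- beta + step * d[1:p]
      cc_new <- cc + step * d[p + 1]
      eta_new <- as.numeric(X %*% beta_new) + cc_new
      obj_new <- obj_of(eta_new, beta_new)
      if (obj_new <= obj + 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    if (obj_new > obj) break   # no descent possible
    beta <- beta_new; cc <- cc_new; eta <- eta_new; obj <- obj_new
    obj_trace <- c(obj_trace, obj)
  }
  bias_raw <- cc - sum(m * beta)
  structure(list(
    template = devectorize(beta, n_time, n_freq),
    bias = bias_raw,
    penalty_weight = penalty_weight,
    penalty_matrix_spec = "laplacian_neumann",
    converged = converged,
    final_objective = obj,
    objective_trace = obj_trace,
    n_trials_used = n,
    n_iter = it,
    grid = c(n_time, n_freq),
    time_bin = table$time_bin,
    center_freqs = table$center_freqs
  ), class = "aci_model")
}

#' Predicted response probabilities from a fitted model
#'
#' @param object an `aci_model`.
#' @param newdata a `trial_table` or pixel matrix.
#' @param ... unused.
#' @return vector of probabilities of responding 'ga'.
#' @export
predict.aci_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "trial_table")) newdata$X else newdata
  beta <- vectorize(object$template)
  if (ncol(X) != length(beta)) stop("pixel-grid mismatch")
  stats::plogis(as.numeric(X %*% beta) + object$bias)
}

# Stratified (by response) fold assignment; folds are redrawn (with a
# message) if any fold ends up single-class.
make_folds <- function(response, n_folds, seed = 1L) {
  n <- length(response)
  stopifnot(n >= n_folds)
  for (attempt in 1:20) {
    folds <- with_seed(derive_seed(seed, 20L + attempt), {
      f <- integer(n)
      for (cls in unique(response)) {
        idx <- which(response == cls)
        f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      f
    })
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(response[folds == k])) == 2
    }, TRUE))
    if (ok) return(folds)
    message("fold with a single response class; redrawing folds")
  }
  stop("could not build folds with both response classes present")
}

#' Cross-validated deviance of a penalty value
#'
#' Mean held-out deviance over stratified folds for one table and one
#' penalty weight.
#'
#' @param table balanced `trial_table`.
#' @param penalty_weight penalty value.
#' @param n_folds number of folds.
#' @param K optional penalty matrix (computed from the grid if omitted).
#' @param seed fold seed.
#' @return mean held-out deviance (scalar).
#' @export
cv_deviance <- function(table, penalty_weight, n_folds = 10, K = NULL,
                        seed = 1L) {
  if (is.null(K)) K <- laplacian_penalty(table$grid[1], table$grid[2])
  folds <- make_folds(table$response, n_folds, seed)
  devs <- vapply(seq_len(n_folds), function(k) {
    fit <- fit_aci(table_subset(table, folds != k), penalty_weight, K = K)
    held <- table_subset(table, folds == k)
    deviance_score(predict(fit, held), held$response)
  }, 0)
  mean(devs)
}

#' Select the smoothness penalty by cross-validation
#'
#' For each candidate penalty, computes the mean cross-validated deviance
#' across all supplied listeners' tables and returns the minimizer (ties
#' broken toward the larger, smoother value). One shared penalty is then
#' applied to all estimations. A warning is recorded when the minimum sits
#' at a grid edge.
#'
#' @param tables list of balanced `trial_table`s.
#' @param penalty_grid numeric vector (>= 2 positive values; typically
#'   log-spaced).
#' @param n_folds folds per table.
#' @param seed fold seed.
#' @return selected penalty (scalar) with attribute `curve`, a data.frame
#'   of (penalty, mean_cv_deviance).
#' @export
select_penalty <- function(tables, penalty_grid, n_folds = 10, seed = 1L) {
  stopifnot(length(tables) >= 1, length(penalty_grid) >= 2,
            all(penalty_grid > 0))
  grid <- sort(penalty_grid)
  Ks <- list()
  curve <- vapply(grid, function(lam) {
    mean(vapply(seq_along(tables), function(i) {
      tab <- tables[[i]]
      key <- paste(tab$grid, collapse = "x")
      if (is.null(Ks[[key]])) {
        Ks[[key]] <<- laplacian_penalty(tab$grid[1], tab$grid[2])
      }
      cv_deviance(tab, lam, n_folds = n_folds, K = Ks[[key]],
                  seed = derive_seed(seed, i))
    }, 0))
  }, 0)
  best <- max(which(curve == min(curve)))   # ties toward smoother
  if (best %in% c(1L, length(grid))) {
    warning("cross-validated deviance minimized at the penalty-grid edge")
  }
  structure(grid[best],
            curve = data.frame(penalty = grid, mean_cv_deviance = curve))
}

#' Default log-spaced penalty grid
#'
#' @param n number of values.
#' @param from,to log10 range.
#' @return numeric vector.
#' @export
default_penalty_grid <- function(n = 15, from = -4, to = 2) {
  10^seq(from, to, length.out = n)
}

#' Z-score a classification image
#'
#' `(beta - mean(beta)) / sd(beta)` over all pixels (sample standard
#' deviation); the bias is excluded. Individual z-scoring puts listeners'
#' templates on a common scale before group averaging.
#'
#' @param model an `aci_model` or a template matrix.
#' @return z-scored template matrix.
#' @export
zscore_aci <- function(model) {
  tpl <- if (inherits(model, "aci_model")) model$template else model
  s <- stats::sd(as.vector(tpl))
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant template (zero variance)")
  }
  (tpl - mean(tpl)) / s
}
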