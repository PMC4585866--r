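make_fake_table <- function(n_correct, n_error, seed = 1) {
  n <- n_correct + n_error
  with_seed(seed, {
    correct <- sample(rep(c(TRUE, FALSE), c(n_correct, n_error)))
    trial_table(X = matrix(rnorm(n * 4), n), response = rbinom(n, 1, 0.5),
                correct = correct, grid = c(2L, 2L))
  })
}

test_that("balancing equates correct and error counts", {
  # the staircase's ~79% correct over 10,000 trials leaves ~2,100 errors,
  # so ~4,200 trials survive balancing
  tab <- make_fake_table(7900, 2100)
  bal <- balance_trials(tab, seed = 3)
  expect_equal(length(bal$response), 4200L)
  expect_equal(sum(bal$correct), sum(!bal$correct))
  expect_true(bal$balanced)
  # order of retained trials is preserved
  expect_true(all(diff(which(tab$correct)[1]) >= 0))
  # already balanced: untouched
  tab2 <- make_fake_table(50, 50)
  bal2 <- balance_trials(tab2, seed = 3)
  expect_equal(bal2$response, tab2$response)
  # no errors: explicit failure
  tab3 <- make_fake_table(100, 0)
  expect_error(balance_trials(tab3), "zero error")
})

test_that("the unpenalized fit matches an independent logistic oracle", {
  set.seed(17)
  n <- 120; p <- 12
  X <- matrix(rnorm(n * p), n)
  beta_true <- rnorm(p, sd = 0.3)
  y <- rbinom(n, 1, plogis(X %*% beta_true))
  tab <- trial_table(X, y, correct = rep(TRUE, n), grid = c(3L, 4L),
                     balanced = TRUE)
  fit <- fit_aci(tab, penalty_weight = 0)
  oracle <- glm(y ~ X, family = binomial)
  expect_lt(max(abs(vectorize(fit$template) - coef(oracle)[-1]) /
                  pmax(abs(coef(oracle)[-1]), 1e-6)), 1e-4)
  expect_equal(fit$bias, unname(coef(oracle)[1]), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("the penalty-dominated limit shrinks the template to zero", {
  set.seed(18)
  n <- 200; X <- matrix(rnorm(n * 16), n)
  y <- rep(0:1, n / 2)   # balanced responses
  tab <- trial_table(X, y, correct = rep(TRUE, n), grid = c(4L, 4L),
                     balanced = TRUE)
  f6 <- fit_aci(tab, 1e6)
  f10 <- fit_aci(tab, 1e10)
  expect_lt(max(abs(f10$template)), 1e-2)
  expect_lt(max(abs(f10$template)), max(abs(f6$template)))
  expect_equal(f10$bias, qlogis(mean(y)), tolerance = 1e-2)  # = 0 balanced
  expect_error(fit_aci(trial_table(X, rep(1L, n), correct = rep(TRUE, n),
                                   grid = c(4L, 4L), balanced = TRUE), 1),
               "degenerate")
})

test_that("the objective decreases monotonically over iterations", {
  bal <- big_balanced()
  idx <- seq_len(1200)
  fit <- fit_aci(subset_trials(bal, idx), 0.01)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  # refitting is bit-reproducible
  fit2 <- fit_aci(subset_trials(bal, idx), 0.01)
  expect_identical(fit$template, fit2$template)
})

test_that("the template is recovered from a simulated observer", {
  bal <- big_balanced()
  truth <- as.vector(small_template())
  fit <- fit_aci(bal, penalty_weight = 0.01)
  expect_gt(cor(as.vector(fit$template), truth), 0.8)
  # recovery improves with trial count (within sampling error)
  cors <- vapply(c(400, 1600, 4000), function(n) {
    f <- fit_aci(subset_trials(bal, seq_len(n)), 0.01)
    cor(as.vector(f$template), truth)
  }, 0)
  expect_true(all(diff(cors) > -0.03))
  expect_gt(cors[3], cors[1])
})

test_that("cross-validated penalty selection finds an interior optimum consistently", {
  bal <- big_balanced()
  grid <- 10^seq(-4, 1, by = 1)
  # two disjoint 'groups' of listeners simulated from the same population
  g1 <- list(subset_trials(bal, 1:1400),
             subset_trials(bal, 1401:2800))
  g2 <- list(subset_trials(bal, 2801:4100))
  s1 <- select_penalty(g1, grid, n_folds = 5, seed = 2)
  s2 <- select_penalty(g2, grid, n_folds = 5, seed = 9)
  curve <- attr(s1, "curve")$mean_cv_deviance
  best <- which.min(curve)
  expect_gt(best, 1)                      # interior minimum
  expect_lt(best, length(grid))
  expect_equal(as.numeric(s1), as.numeric(s2))  # same penalty in both groups
  # degenerate grid still returns the shared value
  one <- suppressWarnings(select_penalty(g2, c(0.01, 0.01), n_folds = 4,
                                         seed = 2))
  expect_equal(as.numeric(one), 0.01)
  # boundary minimum is flagged
  expect_warning(select_penalty(g2, c(1e4, 1e6), n_folds = 4, seed = 2),
                 "edge")
})

test_that("z-scoring standardizes templates and rejects constants", {
  set.seed(30)
  tpl <- matrix(rnorm(24, 2, 3), 4, 6)
  z <- zscore_aci(tpl)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(z)), 1, tolerance = 1e-12)
  expect_equal(zscore_aci(2.5 * tpl + 7), z)   # affine invariance
  expect_error(zscore_aci(matrix(3, 4, 6)), "constant")
})

test_that("the smoothness penalty is the squared Laplacian plus a vanishing ridge", {
  K <- laplacian_penalty(3, 3, ridge = 0)
  # constant maps are in the Laplacian nullspace
  expect_equal(max(abs(as.numeric(K %*% rep(1, 9)))), 0)
  # symmetric positive semidefinite
  expect_equal(as.matrix(K), t(as.matrix(K)))
  ev <- eigen(as.matrix(K), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  # a smooth ramp is penalized less than a checkerboard
  ramp <- as.vector(t(matrix(rep(1:3, each = 3), 3)))
  checker <- rep(c(1, -1), length.out = 9) * 2
  q <- function(v) sum(v * as.numeric(K %*% v))
  expect_lt(q(ramp / sqrt(sum(ramp^2))), q(checker / sqrt(sum(checker^2))))
})
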