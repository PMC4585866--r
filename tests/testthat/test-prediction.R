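test_that("deviance and accuracy follow their closed forms", {
  r <- rep(c(0L, 1L), 50)
  expect_equal(deviance_score(ifelse(r == 1, 1, 0), r), 0, tolerance = 1e-9)
  expect_equal(deviance_score(rep(0.5, 100), r), 100 * 2 * log(2))
  set.seed(2)
  p <- runif(100)
  expect_gte(deviance_score(p, r), 0)
  expect_error(deviance_score(p[-1], r), "length")
  # tie rule: probabilities exactly at 0.5 count as incorrect
  expect_equal(accuracy_score(c(0.5, 0.9, 0.1), c(0L, 1L, 0L)), 2 / 3)
})

test_that("cross-prediction of a table against itself reproduces auto-prediction", {
  bal <- subset_trials(big_balanced(), 1:800)
  a <- auto_prediction(bal, 0.01, n_folds = 5, seed = 3)
  x <- cross_prediction(bal, bal, 0.01, n_folds = 5, seed = 3)
  expect_equal(a$deviance, x$deviance)
  expect_equal(a$accuracy, x$accuracy)
  expect_gte(a$deviance, 0)
})

test_that("auto-prediction is at chance for coin-flip responses and high for deterministic observers", {
  # zero-template observer: responses are fair coin flips
  zero_obs <- observer_spec(matrix(0, 16, 12), gain = 1)
  tab0 <- simulate_trials(zero_obs, small_targets(), small_fb(), 1300, -6,
                          seed = 12L)
  bal0 <- balance_trials(tab0, 1)
  a0 <- auto_prediction(bal0, 0.01, n_folds = 5, seed = 4)
  expect_equal(a0$accuracy, 0.5, tolerance = 0.06)
  # near-deterministic observer: responses are a function of the stimulus
  det_obs <- observer_spec(small_observer()$template,
                           gain = 1e5 * small_observer()$gain,
                           center = small_observer()$center)
  tabd <- simulate_trials(det_obs, small_targets(), small_fb(), 1300, -6,
                          seed = 13L)
  bald <- balance_trials(tabd, 1)
  ad <- auto_prediction(bald, 0.01, n_folds = 5, seed = 4)
  expect_gt(ad$accuracy, 0.75)
  expect_gt(ad$accuracy, a0$accuracy + 0.15)
})

test_that("cross-prediction tracks template similarity", {
  fb <- small_fb()
  twin1 <- small_observer()
  tab_a <- balance_trials(simulate_trials(twin1, small_targets(), fb, 1300,
                                          -6, seed = 21L), 1)
  tab_b <- balance_trials(simulate_trials(twin1, small_targets(), fb, 1300,
                                          -6, seed = 22L), 1)
  auto_a <- auto_prediction(tab_a, 0.01, n_folds = 5, seed = 5)
  cross_ab <- cross_prediction(tab_a, tab_b, 0.01, n_folds = 5, seed = 5)
  # twin observers: cross ~ auto
  expect_equal(cross_ab$accuracy, auto_a$accuracy, tolerance = 0.08)
  # orthogonal-template observer: its decision variable is decorrelated
  # from the shared template's decision variable over the stimulus
  # ensemble (pixel-space orthogonality alone leaves correlation through
  # the stimulus covariance), so cross-prediction drops to chance
  tpl <- small_template()
  ref <- fx_get("ref_stimuli", function() {
    reference_stimuli(small_targets(), small_fb(), n_trials = 400,
                      snr_db = -6, seed = 2L)
  })
  raw <- matrix(0, nrow(tpl), ncol(tpl))
  raw[seq(1, length(raw), by = 2)] <- as.vector(tpl)[seq(2, length(tpl),
                                                         by = 2)]
  Xc <- scale(ref$X, scale = FALSE)
  # decorrelate from the shared template AND from the class signal
  mdiff <- devectorize(colMeans(ref$X[ref$truth == 1, ]) -
                         colMeans(ref$X[ref$truth == 0, ]), 16, 12)
  A <- cbind(as.numeric(Xc %*% vectorize(tpl)),
             as.numeric(Xc %*% vectorize(mdiff)))
  dv_r <- as.numeric(Xc %*% vectorize(raw))
  cf <- solve(crossprod(A) + 1e-8 * diag(2), crossprod(A, dv_r))
  orth <- raw - cf[1] * tpl - cf[2] * mdiff
  orth <- orth / sqrt(sum(orth^2))
  dv_o <- as.numeric(Xc %*% vectorize(orth))
  expect_lt(abs(cor(dv_o, A[, 1])), 0.1)
  expect_lt(abs(cor(dv_o, ref$truth)), 0.1)
  obs_o <- centered_observer(orth, 99L)
  tab_o <- balance_trials(simulate_trials(obs_o, small_targets(), fb, 1300,
                                          -6, seed = 23L), 1)
  cross_ao <- cross_prediction(tab_a, tab_o, 0.01, n_folds = 5, seed = 5)
  expect_lt(abs(cross_ao$accuracy - 0.5), 0.05)
  expect_gt(cross_ab$accuracy, cross_ao$accuracy + 0.1)
  expect_error(cross_prediction(tab_a,
                                trial_table(matrix(0, 20, 6),
                                            rep(0:1, 10), rep(TRUE, 20),
                                            grid = c(2L, 3L)), 0.01),
               "grids")
})

test_that("specificity is negative for idiosyncratic observers and near zero for clones", {
  fb <- small_fb()
  # three listeners with distinctly jittered templates
  tabs <- lapply(1:3, function(i) {
    obs <- jitter_observer(1.2, 50L + i)
    balance_trials(simulate_trials(obs, small_targets(), fb, 1100, -6,
                                   seed = 60L + i), 1)
  })
  names(tabs) <- paste0("L", 1:3)
  pm <- prediction_matrix(tabs, 0.01, n_folds = 5, seed = 6)
  sp <- specificity_score(pm)
  expect_length(sp, 3L)
  # own model fits own data best: lower deviance on the diagonal
  expect_true(all(sp < 0))
  expect_equal(sp[["L1"]],
               pm$deviance[1, 1] - mean(pm$deviance[2:3, 1]))
  expect_error(specificity_score(
    structure(list(deviance = matrix(1), listeners = "a"),
              class = "prediction_matrix")), "two listeners")
})

test_that("signal-detection metrics match their closed forms", {
  # symmetric rates: no sensitivity, no bias
  tab <- list(response = c(rep(0:1, 50), rep(0:1, 50)),
              target_id = rep(c("alga", "alda"), each = 100))
  m <- sdt_metrics(tab)
  expect_equal(m$d_prime, 0)
  expect_equal(m$criterion, 0)
  # hit 0.84 / fa 0.16: d' ~ 1.99
  tab2 <- list(response = c(rep(1L, 84), rep(0L, 16), rep(1L, 16), rep(0L, 84)),
               target_id = rep(c("arga", "arda"), each = 100))
  m2 <- sdt_metrics(tab2)
  expect_equal(m2$d_prime, qnorm(0.84) - qnorm(0.16), tolerance = 1e-12)
  expect_equal(round(m2$d_prime, 2), 1.99)
  # extreme rates corrected by the 1/(2N) rule
  tab3 <- list(response = c(rep(1L, 100), rep(0L, 50), rep(1L, 50)),
               target_id = rep(c("alga", "alda"), c(100, 100)))
  m3 <- sdt_metrics(tab3)
  expect_equal(m3$hit_rate, 1 - 1 / 200)
  expect_error(sdt_metrics(list(response = rep(1L, 10),
                                target_id = rep("alga", 10))), "classes")
})
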