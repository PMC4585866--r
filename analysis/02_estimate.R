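# Estimate each listener's Auditory Classification Image: rebuild the
# stimuli from the trial logs, balance correct/error trials, select one
# shared smoothness penalty by cross-validated deviance, fit the penalized
# logistic model, and z-score the templates. Writes the penalty curve,
# per-listener fit summaries, and one z-scored map per listener.

source("analysis/00_config.R")

targets <- default_targets(analysis_timing(), seed = MASTER_SEED)
fb <- analysis_filterbank()
ids <- listener_ids()
paths <- file.path(OUT_DIR, paste0("trials_", ids, ".tsv"))
stopifnot(`run 01_simulate.R first` = all(file.exists(paths)))

cat("Rebuilding stimuli and cochleograms from the trial logs...\n")
tables <- import_trial_logs(paths, targets, fb)
names(tables) <- ids

balanced <- lapply(seq_along(tables), function(i) {
  balance_trials(tables[[i]], seed = MASTER_SEED + 200L + i)
})
names(balanced) <- ids
cat("Balanced trial counts:",
    paste(vapply(balanced, function(t) length(t$response), 0L),
          collapse = ", "), "\n")

cat("Selecting the shared smoothness penalty by", N_FOLDS,
    "fold cross-validation...\n")
penalty <- select_penalty(balanced, PENALTY_GRID, n_folds = N_FOLDS,
                          seed = MASTER_SEED + 300L)
curve <- attr(penalty, "curve")
save_table(curve, "penalty_curve.tsv")
cat("Selected penalty:", as.numeric(penalty), "\n")
print(curve, row.names = FALSE)

K <- laplacian_penalty(balanced[[1]]$grid[1], balanced[[1]]$grid[2])
fits <- lapply(balanced, fit_aci, penalty_weight = as.numeric(penalty),
               K = K)
zmaps <- lapply(fits, zscore_aci)
for (i in seq_along(ids)) {
  save_map(zmaps[[i]], paste0("zmap_", ids[i], ".tsv"))
}

fit_summary <- data.frame(
  listener = ids,
  group = c("control", "focused")[listener_groups()],
  n_trials_used = vapply(fits, `[[`, 0L, "n_trials_used"),
  bias = vapply(fits, `[[`, 0, "bias"),
  converged = vapply(fits, `[[`, TRUE, "converged"),
  n_iter = vapply(fits, `[[`, 0L, "n_iter"))
save_table(fit_summary, "fit_summary.tsv")
save_table(data.frame(penalty = as.numeric(penalty)), "selected_penalty.tsv")

cat("\nAll", sum(fit_summary$converged), "of", nrow(fit_summary),
    "fits converged.\n")
cat("Wrote penalty_curve.tsv, fit_summary.tsv and one z-scored map per",
    "listener.\n")
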