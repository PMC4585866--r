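# Simulate the listening experiment: for each of the ten listeners, a
# 3-down-1-up adaptive session of /da/-/ga/ categorization in white noise.
# Writes one trial log per listener plus a performance summary.

source("analysis/00_config.R")

targets <- default_targets(analysis_timing(), seed = MASTER_SEED)
fb <- analysis_filterbank()
observers <- build_observers(targets, fb)
ids <- listener_ids()

cat("Simulating", length(ids), "listeners x",
    N_SESSIONS * TRIALS_PER_SESSION, "trials...\n")

dir.create(OUT_DIR, recursive = TRUE, showWarnings = FALSE)

cfg <- experiment_config(n_sessions = N_SESSIONS,
                         trials_per_session = TRIALS_PER_SESSION,
                         store_cochleograms = FALSE)

rows <- vector("list", length(ids))
for (i in seq_along(ids)) {
  log <- simulate_experiment(observers[[i]], targets, fb, cfg,
                             seed = MASTER_SEED + 100L + i)
  write_trial_log(log, file.path(OUT_DIR, paste0("trials_", ids[i], ".tsv")))
  rows[[i]] <- data.frame(
    listener = ids[i],
    group = c("control", "focused")[listener_groups()[i]],
    pct_correct = 100 * mean(log$trials$correct),
    mean_snr_db = mean(log$trials$snr_db),
    final_snr_db = log$trials$snr_db[nrow(log$trials)],
    n_errors = sum(!log$trials$correct))
  cat(sprintf("  %s: %.1f%% correct, mean SNR %.2f dB\n", ids[i],
              rows[[i]]$pct_correct, rows[[i]]$mean_snr_db))
}

perf <- do.call(rbind, rows)
save_table(perf, "listener_performance.tsv")

cat("\nGroup means:\n")
agg <- aggregate(cbind(pct_correct, mean_snr_db) ~ group, perf, mean)
print(agg, row.names = FALSE)
cat("\nThe staircase holds both groups near the 79.4% fixed point;\n")
cat("per-listener SNR varies with template quality.\n")
cat("Wrote", nrow(perf), "trial logs and listener_performance.tsv\n")
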