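# Orchestration: simulate a whole two-group study end to end, and
# serialize/deserialize trial logs in a schema compatible with deposited
# experiment data (one delimited-text row per trial plus a JSON config
# sidecar).

#' Default study configuration
#'
#' All defaults equal the study conditions of the experiment being
#' emulated (20 sessions of 500 trials, initial SNR -11 dB, 2 dB step
#' decaying 10% per change to 0.2 dB, 54-channel 96-7760 Hz cochleogram
#' binned at 15.6 ms, 19 listeners per group); reduced-scale overrides are
#' recorded in the run manifest.
#'
#' @param n_per_group listeners per group.
#' @param n_sessions,trials_per_session staircase schedule.
#' @param timing target timing from [vccv_timing()].
#' @param frontend filterbank arguments (list passed to
#'   [make_filterbank()]); `sample_rate` is taken from `timing`.
#' @param penalty_grid candidate smoothness penalties.
#' @param n_folds cross-validation folds.
#' @param observer_gain gain of the simulated listeners (`NULL` to
#'   calibrate by bisection at `calibration_snr`).
#' @param calibration_snr SNR used when calibrating the gain.
#' @param template_jitter_sd per-listener heterogeneity: s.d. of Gaussian
#'   perturbations added to the shared ideal template (relative to the
#'   template's own pixel s.d.).
#' @param group2_boost multiplicative weight amplification applied to
#'   group 2's templates inside the amplified region (an injected group
#'   difference; 1 = none).
#' @param group2_region amplified region: either
#'   `list(time = rows, freq = cols)` of pixel indices, or
#'   `list(cue_quantile = q)` to amplify the core negative cue lobe — the
#'   pixels where the shared ideal template falls below its `q`-quantile,
#'   a sign-coherent region, so the induced group difference is spatially
#'   contiguous (the focused-listener pattern the group statistics are
#'   designed to detect).
#' @param fdr_q FDR level for the group maps.
#' @param cluster_alpha pixel-inclusion alpha of the cluster test.
#' @param n_permutations permutations for the cluster test.
#' @return named list.
#' @export
study_config <- function(n_per_group = 19, n_sessions = 20,
                         trials_per_session = 500,
                         timing = vccv_timing(),
                         frontend = list(n_channels = 54, f_lo = 96,
                                         f_hi = 7760, q = 8,
                                         time_bin = 0.0156),
                         penalty_grid = default_penalty_grid(),
                         n_folds = 10, observer_gain = NULL,
                         calibration_snr = -12,
                         template_jitter_sd = 0.5, group2_boost = 1,
                         group2_region = NULL, fdr_q = 0.01,
                         cluster_alpha = 0.05, n_permutations = 1000) {
  list(n_per_group = n_per_group, n_sessions = n_sessions,
       trials_per_session = trials_per_session, timing = timing,
       frontend = frontend, penalty_grid = penalty_grid, n_folds = n_folds,
       observer_gain = observer_gain, calibration_snr = calibration_snr,
       template_jitter_sd = template_jitter_sd, group2_boost = group2_boost,
       group2_region = group2_region, fdr_q = fdr_q,
       cluster_alpha = cluster_alpha, n_permutations = n_permutations)
}

#' Run a complete simulated two-group study
#'
#' Builds the four targets and the filterbank, creates two populations of
#' linear observers (a shared ideal template with per-listener jitter;
#' group 2 optionally amplified in a designated region), runs the adaptive
#' experiment for each listener, balances trials, selects one shared
#' smoothness penalty by cross-validation, fits and z-scores all
#' classification images, computes the prediction matrix, specificity and
#' signal-detection metrics, and runs the group statistics. All artifacts
#' are written as delimited text/JSON under `out_dir` with an md5
#' manifest; a run is fully reproducible from (config, seed).
#'
#' @param config list from [study_config()].
#' @param seed master seed.
#' @param out_dir output directory (`NULL` to skip writing).
#' @return study bundle (list), invisibly when writing.
#' @export
run_simulated_study <- function(config = study_config(), seed = 1L,
                                out_dir = NULL) {
  targets <- default_targets(config$timing, seed = derive_seed(seed, 100L))
  fb_args <- config$frontend
  fb_args$sample_rate <- config$timing$sample_rate
  fb <- do.call(make_filterbank, fb_args)

  target_cochs <- lapply(targets, compute_cochleogram, fb = fb)
  labels <- vapply(targets, `[[`, "", "consonant_label")
  base_tpl <- ideal_template_from_targets(target_cochs, labels)
  ref <- reference_stimuli(targets, fb, snr_db = config$calibration_snr,
                           seed = derive_seed(seed, 101L))
  base_obs <- calibrate_gain(base_tpl, targets, fb,
                             snr_db = config$calibration_snr,
                             seed = derive_seed(seed, 101L), ref = ref)
  gain <- config$observer_gain %||% base_obs$gain

  n_g <- config$n_per_group
  n_all <- 2L * n_g
  group <- rep(c(1L, 2L), each = n_g)
  boost_mask <- NULL
  if (config$group2_boost != 1 && !is.null(config$group2_region)) {
    rg <- config$group2_region
    boost_mask <- matrix(FALSE, nrow(base_tpl), ncol(base_tpl))
    if (!is.null(rg$cue_quantile)) {
      boost_mask[base_tpl <= stats::quantile(base_tpl, rg$cue_quantile)] <- TRUE
    } else {
      boost_mask[rg$time, rg$freq] <- TRUE
    }
  }
  observers <- lapply(seq_len(n_all), function(i) {
    tpl <- base_tpl + with_seed(
      derive_seed(seed, 200L + i),
      matrix(rnorm(length(base_tpl),
                   sd = config$template_jitter_sd * stats::sd(base_tpl)),
             nrow(base_tpl)))
    if (group[i] == 2L && !is.null(boost_mask)) {
      tpl[boost_mask] <- tpl[boost_mask] * config$group2_boost
    }
    tpl <- tpl / sqrt(sum(tpl^2))
    dv <- as.numeric(ref$X %*% vectorize(tpl))
    center <- (mean(dv[ref$truth == 1]) + mean(dv[ref$truth == 0])) / 2
    observer_spec(tpl, gain = gain, center = center,
                  seed = derive_seed(seed, 200L + i))
  })

  exp_cfg <- experiment_config(n_sessions = config$n_sessions,
                               trials_per_session = config$trials_per_session)
  logs <- lapply(seq_len(n_all), function(i) {
    simulate_experiment(observers[[i]], targets, fb, exp_cfg,
                        seed = derive_seed(seed, 300L + i))
  })
  tables <- lapply(seq_len(n_all), function(i) {
    balance_trials(log_to_table(logs[[i]], fb),
                   seed = derive_seed(seed, 400L + i))
  })
  names(tables) <- sprintf("%s%02d", c("C", "M")[group], seq_len(n_all))

  penalty <- select_penalty(tables, config$penalty_grid,
                            n_folds = config$n_folds,
                            seed = derive_seed(seed, 500L))
  K <- laplacian_penalty(tables[[1]]$grid[1], tables[[1]]$grid[2])
  fits <- lapply(tables, fit_aci, penalty_weight = as.numeric(penalty), K = K)
  z_maps <- lapply(fits, zscore_aci)

  pm <- prediction_matrix(tables, as.numeric(penalty),
                          n_folds = config$n_folds,
                          seed = derive_seed(seed, 600L))
  spec <- specificity_score(pm)
  # sensitivity/criterion from the full runs (balancing forces hit and
  # false-alarm rates to 0.5 by construction)
  sdt <- lapply(logs, function(l) sdt_metrics(l$trials))

  g1 <- z_maps[group == 1L]; g2 <- z_maps[group == 2L]
  fdr1 <- pixel_ttest_fdr(g1, q = config$fdr_q)
  fdr2 <- pixel_ttest_fdr(g2, q = config$fdr_q)
  clus <- cluster_permutation_test(g1, g2,
                                   alpha_threshold = config$cluster_alpha,
                                   n_permutations = config$n_permutations,
                                   seed = derive_seed(seed, 700L))
  sets <- extract_weight_sets(z_maps, time_bin = fb$time_bin,
                              center_freqs = fb$center_freqs)
  roi <- roi_group_test(sets, g1, g2)

  listener_summary <- data.frame(
    listener = names(tables),
    group = c("group1", "group2")[group],
    pct_correct = vapply(logs, function(l) 100 * mean(l$trials$correct), 0),
    mean_snr = vapply(logs, function(l) mean(l$trials$snr_db), 0),
    n_balanced = vapply(tables, function(t) length(t$response), 0),
    auto_deviance = diag(pm$deviance),
    auto_accuracy = diag(pm$accuracy),
    specificity = as.numeric(spec),
    d_prime = vapply(sdt, `[[`, 0, "d_prime"),
    criterion = vapply(sdt, `[[`, 0, "criterion"),
    row.names = NULL)

  bundle <- list(config = config, seed = as.integer(seed),
                 filterbank = fb, penalty = as.numeric(penalty),
                 penalty_curve = attr(penalty, "curve"),
                 logs = logs, tables = tables, fits = fits,
                 z_maps = z_maps, prediction = pm, specificity = spec,
                 sdt = sdt, group = group, fdr_group1 = fdr1,
                 fdr_group2 = fdr2, cluster_test = clus,
                 weight_sets = sets, roi = roi,
                 listener_summary = listener_summary)
  if (!is.null(out_dir)) {
    write_study(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

write_matrix_tsv <- function(m, path) {
  utils::write.table(format(m, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
}

#' Write a study bundle to disk
#'
#' Trial logs, listener summary, penalty curve, z-scored maps, prediction
#' matrices, cluster/ROI tables, and a JSON manifest with md5 checksums of
#' every written file.
#'
#' @param bundle result of [run_simulated_study()].
#' @param out_dir output directory (created if missing).
#' @return manifest path, invisibly.
#' @export
write_study <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  save_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  for (i in seq_along(bundle$logs)) {
    id <- bundle$listener_summary$listener[i]
    write_trial_log(bundle$logs[[i]],
                    file.path(out_dir, paste0("trials_", id, ".tsv")))
    files <- c(files, file.path(out_dir, paste0("trials_", id, ".tsv")),
               file.path(out_dir, paste0("trials_", id, ".json")))
  }
  save_tsv(bundle$listener_summary, "listener_summary.tsv")
  save_tsv(bundle$penalty_curve, "penalty_curve.tsv")
  save_tsv(as.data.frame(bundle$prediction$deviance), "prediction_deviance.tsv")
  save_tsv(as.data.frame(bundle$prediction$accuracy), "prediction_accuracy.tsv")
  save_tsv(bundle$cluster_test$clusters, "cluster_test.tsv")
  save_tsv(bundle$roi, "roi_table.tsv")
  for (g in 1:2) {
    fdr <- bundle[[paste0("fdr_group", g)]]
    path <- file.path(out_dir, sprintf("group%d_masked_mean.tsv", g))
    write_matrix_tsv(fdr$masked_mean, path)
    files <- c(files, path)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("aciglm")),
    seed = bundle$seed,
    penalty = bundle$penalty,
    n_listeners = length(bundle$tables),
    files = lapply(sort(files), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}

#' Write an experiment log as delimited text
#'
#' One row per trial (session, trial, target_id, noise_seed, noise_index,
#' snr_db, step_db, response, correct) plus a JSON sidecar with the run
#' configuration and master seed.
#'
#' @param log an `experiment_log`.
#' @param path output `.tsv` path; the sidecar takes the same stem with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  df <- log$trials
  df$noise_seed <- log$noise_seed
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  cfg <- log$config
  cfg$fade <- cfg$fade %||% NA
  jsonlite::write_json(list(seed = log$seed, noise_seed = log$noise_seed,
                            observer_class = log$observer_class,
                            grid = log$grid, config = cfg),
                       sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an experiment log written by [write_trial_log()]
#'
#' @param path `.tsv` path.
#' @return an `experiment_log` (without stored cochleograms).
#' @export
read_trial_log <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("session", "trial", "target_id", "noise_index", "snr_db",
                "step_db", "response", "correct")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("malformed trial log ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  sidecar <- sub("\\.tsv$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  structure(list(
    trials = df[required], X = NULL,
    grid = if (!is.null(meta$grid)) unlist(meta$grid) else NULL,
    config = meta$config, seed = meta$seed %||% df$noise_seed[1] %||% NA,
    noise_seed = meta$noise_seed %||% unique(df$noise_seed)[1],
    observer_class = meta$observer_class %||% NA_character_
  ), class = "experiment_log")
}

#' Import trial logs and rebuild trial tables
#'
#' Reads one or more serialized trial logs and reconstructs each trial's
#' stimulus (target + stored-noise reference mixed at the logged SNR) and
#' its cochleogram, producing `trial_table`s that flow into the same
#' estimation path as freshly simulated data.
#'
#' @param paths character vector of `.tsv` trial-log paths.
#' @param targets named list of `target_signal`s covering every
#'   `target_id` in the logs.
#' @param fb a `filterbank`.
#' @return named list of `trial_table`s.
#' @export
import_trial_logs <- function(paths, targets, fb) {
  n_samples <- length(targets[[1]]$samples)
  out <- lapply(paths, function(path) {
    log <- read_trial_log(path)
    df <- log$trials
    if (is.null(log$noise_seed) || is.na(log$noise_seed)) {
      stop("trial log ", path, " has no noise seed; stimuli cannot be rebuilt")
    }
    bad <- which(!df$target_id %in% names(targets))
    if (length(bad)) {
      stop("trial log ", path, ", trial row ", bad[1],
           ": unknown target '", df$target_id[bad[1]], "'")
    }
    X <- matrix(NA_real_, nrow(df), 0)
    grid <- NULL
    for (i in seq_len(nrow(df))) {
      noise <- generate_noise(n_samples, log$noise_seed,
                              index = df$noise_index[i])
      mix <- mix_at_snr(targets[[df$target_id[i]]], noise, df$snr_db[i])
      coch <- compute_cochleogram(mix, fb)
      if (is.null(grid)) {
        grid <- dim(coch$values)
        X <- matrix(NA_real_, nrow(df), prod(grid))
      }
      X[i, ] <- vectorize(coch)
    }
    trial_table(X = X, response = df$response, correct = df$correct,
                target_id = df$target_id, snr_db = df$snr_db,
                session = df$session, grid = grid,
                time_bin = fb$time_bin, center_freqs = fb$center_freqs)
  })
  names(out) <- sub("\\.tsv$", "", basename(paths))
  out
}
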