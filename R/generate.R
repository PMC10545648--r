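#' Generate a synthetic threshold-tracked awareness dataset
#'
#' Simulates a full study: for each subject an observer is drawn from a
#' population of two-probit psychometric models, an interleaved-staircase
#' session is run (detection and identification staircases plus catch trials),
#' and for every trial a multichannel ERP epoch is simulated, downsampled,
#' baseline corrected, screened for artifacts, and reduced to the two
#' trial-level outcomes (VAN-window and LP-window mean amplitudes). Epochs are
#' processed in a streaming fashion so arbitrarily large sessions fit in
#' memory; set \code{keep_epochs} to retain the first few processed epochs for
#' inspection.
#'
#' Population defaults mirror the study conditions the generator emulates:
#' detection thresholds near 1 and identification thresholds near 2.9 opacity
#' units (between-subject SDs from the condition-wise means), a 0.05 catch
#' probability, and awareness effects of -2.12/-0.46 microvolts (VAN,
#' detection/identification) and +1.83/+0.43 microvolts (LP).
#'
#' @param n_subjects Number of subjects (default 38, the analyzed sample
#'   size the generator emulates).
#' @param n_trials Trials per subject.
#' @param erp An \code{\link{erp_gen_params}} object.
#' @param detect_cfg,identify_cfg Staircase configurations.
#' @param catch_prob Catch-trial probability.
#' @param mode Trial scheduling mode, see \code{\link{run_session}}.
#' @param population Named list of population parameters for observer
#'   sampling: \code{mu_detect_mean}, \code{mu_detect_sd},
#'   \code{mu_identify_mean}, \code{mu_identify_sd}, \code{sigma_detect},
#'   \code{sigma_identify}, \code{false_alarm_rate}, \code{lapse_rate}.
#' @param downsample_factor Integer decimation factor applied to each epoch
#'   before feature extraction (default 2: 512 to 256 Hz).
#' @param keep_epochs Number of leading processed epochs to retain.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return An object of class \code{awareness_dataset}: a list with
#'   \code{trials} (one row per trial with behavioural fields, amplitudes and
#'   artifact flags), \code{ground_truth} (all generating parameters,
#'   per-subject observer parameters and deviations, and per-trial artifact
#'   status), and optionally \code{epochs}.
#' @examples
#' ds <- generate_dataset(n_subjects = 2, n_trials = 40, seed = 1)
#' head(ds$trials)
#' @export
generate_dataset <- function(n_subjects = 38, n_trials = 500,
                             erp = erp_gen_params(),
                             detect_cfg = staircase_config(),
                             identify_cfg = staircase_config(initial_opacity = 8),
                             catch_prob = 0.05,
                             mode = c("bernoulli", "sections"),
                             population = list(),
                             downsample_factor = 2,
                             keep_epochs = 0,
                             seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 1, n_trials >= 1)
  pop <- utils::modifyList(list(mu_detect_mean = 1.05, mu_detect_sd = 0.30,
                                mu_identify_mean = 2.85, mu_identify_sd = 1.20,
                                sigma_detect = 0.30, sigma_identify = 0.45,
                                false_alarm_rate = 0.04, lapse_rate = 0.02),
                           population)
  set.seed(as.integer(seed))
  van_w <- window_spec(erp$van_window[1], erp$van_window[2],
                       erp$van_electrodes)
  lp_w <- window_spec(erp$lp_window[1], erp$lp_window[2], erp$lp_electrodes)
  subjects <- vector("list", n_subjects)
  trial_list <- vector("list", n_subjects)
  artifact_truth <- vector("list", n_subjects)
  kept <- list()
  for (s in seq_len(n_subjects)) {
    mu_d <- max(0.3, stats::rnorm(1, pop$mu_detect_mean, pop$mu_detect_sd))
    mu_i <- max(mu_d + 0.5,
                stats::rnorm(1, pop$mu_identify_mean, pop$mu_identify_sd))
    obs <- observer_params(mu_detect = mu_d, sigma_detect = pop$sigma_detect,
                           mu_identify = mu_i,
                           sigma_identify = pop$sigma_identify,
                           false_alarm_rate = pop$false_alarm_rate,
                           lapse_rate = pop$lapse_rate)
    dev <- stats::rnorm(4, 0, erp$subject_sd)
    names(dev) <- c("van_detect", "van_identify", "lp_detect", "lp_identify")
    ses <- run_session(obs, detect_cfg, identify_cfg, n_trials = n_trials,
                       catch_prob = catch_prob, mode = mode)
    tr <- ses$trials
    n <- nrow(tr)
    van_amp <- numeric(n); lp_amp <- numeric(n)
    rng <- numeric(n); is_art <- logical(n)
    for (i in seq_len(n)) {
      thr <- if (tr$staircase[i] == "identify") "identify" else "detect"
      aware_i <- if (is.na(tr$aware[i])) 0L else tr$aware[i]
      opac_dev <- if (tr$staircase[i] == "catch") 0 else
        tr$opacity[i] - (if (thr == "detect") mu_d else mu_i)
      sdev_van <- if (thr == "detect") dev["van_detect"] else dev["van_identify"]
      sdev_lp <- if (thr == "detect") dev["lp_detect"] else dev["lp_identify"]
      ep <- simulate_epoch(erp, aware = aware_i, threshold = thr,
                           opacity_dev = opac_dev,
                           subject_dev_van = sdev_van,
                           subject_dev_lp = sdev_lp)
      is_art[i] <- attr(ep, "is_artifact")
      ep <- downsample_epoch(ep, downsample_factor)
      ep <- baseline_correct(ep)
      rng[i] <- epoch_range(ep)
      van_amp[i] <- mean_amplitude(ep, van_w)
      lp_amp[i] <- mean_amplitude(ep, lp_w)
      if (length(kept) < keep_epochs) kept[[length(kept) + 1L]] <- ep
    }
    tr$subject_id <- s
    tr$eeg_bad <- flag_artifacts(rng)
    tr$van_amp <- van_amp
    tr$lp_amp <- lp_amp
    tr$block_index <- NA_integer_
    tr$block_valid <- NA
    tr$opacity_centered <- NA_real_
    trial_list[[s]] <- tr
    artifact_truth[[s]] <- is_art
    subjects[[s]] <- data.frame(subject_id = s, mu_detect = mu_d,
                                sigma_detect = pop$sigma_detect,
                                mu_identify = mu_i,
                                sigma_identify = pop$sigma_identify,
                                dev_van_detect = dev[["van_detect"]],
                                dev_van_identify = dev[["van_identify"]],
                                dev_lp_detect = dev[["lp_detect"]],
                                dev_lp_identify = dev[["lp_identify"]])
  }
  trials <- do.call(rbind, trial_list)
  rownames(trials) <- NULL
  cols <- c("subject_id", "trial_index", "staircase", "opacity",
            "opacity_centered", "orientation", "pas", "aware",
            "threshold_dummy", "correct", "block_index", "block_valid",
            "eeg_bad", "van_amp", "lp_amp")
  trials <- trials[, cols]
  structure(list(
    trials = trials,
    ground_truth = list(seed = as.integer(seed),
                        erp = erp, population = pop,
                        detect_cfg = detect_cfg, identify_cfg = identify_cfg,
                        catch_prob = catch_prob, mode = mode,
                        downsample_factor = downsample_factor,
                        subjects = do.call(rbind, subjects),
                        is_artifact = unlist(artifact_truth)),
    epochs = if (keep_epochs > 0) kept else NULL),
    class = "awareness_dataset")
}

#' @export
print.awareness_dataset <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("Synthetic awareness dataset: %d subjects, %d trials (%d catch)\n",
              length(unique(tr$subject_id)), nrow(tr),
              sum(tr$staircase == "catch")))
  cat(sprintf("  seed %d; VAN/LP effects (detect, identify): %.2f/%.2f, %.2f/%.2f uV\n",
              x$ground_truth$seed,
              x$ground_truth$erp$van_effect_detect,
              x$ground_truth$erp$van_effect_identify,
              x$ground_truth$erp$lp_effect_detect,
              x$ground_truth$erp$lp_effect_identify))
  invisible(x)
}

#' Write the trial table to CSV
#'
#' @param dataset An \code{\link{generate_dataset}} result, or a trial data
#'   frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trials_csv <- function(dataset, path) {
  tr <- if (inherits(dataset, "awareness_dataset")) dataset$trials else dataset
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth record to JSON
#'
#' Serializes the generating parameters (seed, ERP and population parameters,
#' staircase configurations, per-subject observer parameters and effect
#' deviations, per-trial artifact status) as JSON.
#'
#' @param dataset An \code{\link{generate_dataset}} result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ground_truth_json <- function(dataset, path) {
  gt <- dataset$ground_truth
  gt$erp <- unclass(gt$erp)
  gt$detect_cfg <- unclass(gt$detect_cfg)
  gt$identify_cfg <- unclass(gt$identify_cfg)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
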