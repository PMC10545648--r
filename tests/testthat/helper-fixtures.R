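# Shared fixture builders (all data generated in code at test time).

# Minimal trial table with the columns the selection stage consumes.
make_trials <- function(subject_id, staircase, aware,
                        opacity = NULL, van_amp = 0, lp_amp = 0,
                        eeg_bad = FALSE, correct = 1L,
                        orientation = "left") {
  n <- length(aware)
  data.frame(subject_id = rep_len(subject_id, n),
             trial_index = seq_len(n) - 1L,
             staircase = rep_len(staircase, n),
             opacity = if (is.null(opacity)) rep(1, n) else
               rep_len(opacity, n),
             opacity_centered = NA_real_,
             orientation = rep_len(orientation, n),
             pas = rep_len(1L, n),
             aware = as.integer(aware),
             threshold_dummy = ifelse(rep_len(staircase, n) == "detect",
                                      1L, 0L),
             correct = rep_len(as.integer(correct), n),
             block_index = NA_integer_,
             block_valid = NA,
             eeg_bad = rep_len(eeg_bad, n),
             van_amp = rep_len(van_amp, n),
             lp_amp = rep_len(lp_amp, n),
             stringsAsFactors = FALSE)
}

# Hierarchical trial data with known fixed effects, for sampler checks.
make_regression_data <- function(n_subjects = 8, n_per = 60,
                                 beta = c(intercept = 0.5, awareness = -2,
                                          opacity = -3),
                                 subject_sd = 0.6, resid_sd = 4, df = 6,
                                 seed = 3) {
  set.seed(seed)
  N <- n_subjects * n_per
  subj <- rep(seq_len(n_subjects), each = n_per)
  aware <- stats::rbinom(N, 1, 0.5)
  opac <- stats::rnorm(N, 0, 0.3)
  u <- matrix(stats::rnorm(n_subjects * 3, 0, subject_sd), n_subjects, 3)
  y <- (beta[1] + u[subj, 1]) + aware * (beta[2] + u[subj, 2]) +
    opac * (beta[3] + u[subj, 3]) + resid_sd * stats::rt(N, df)
  data.frame(subject_id = subj, staircase = "detect",
             threshold_dummy = 1L, aware = aware, opacity_centered = opac,
             orientation = sample(c("left", "right"), N, replace = TRUE),
             van_amp = y, lp_amp = y, stringsAsFactors = FALSE)
}

# A constant-valued epoch for feature tests.
constant_epoch <- function(value = 1, channels = c("O1", "O2", "Pz"),
                           sample_rate = 256) {
  times <- vanlp:::epoch_times(sample_rate)
  erp_epoch(matrix(value, length(channels), length(times)),
            channels, times, sample_rate)
}
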