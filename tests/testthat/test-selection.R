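# Brute-force oracle: widest symmetric aware-count range around n/2 whose
# exact binomial probability stays below the criterion.
oracle_range <- function(n, criterion) {
  best <- c(NA_integer_, NA_integer_)
  for (k in 0:(n / 2)) {
    p <- sum(dbinom((n / 2 - k):(n / 2 + k), n, 0.5))
    if (p < criterion) best <- c(n / 2 - k, n / 2 + k) else break
  }
  best
}

test_that("block-validity ranges reproduce the standard presets", {
  expect_equal(valid_block_range(16, 0.80), c(6, 10))
  expect_equal(valid_block_range(16, 0.55), c(7, 9))
  expect_equal(valid_block_range(20, 0.75), c(8, 12))
  expect_equal(valid_block_range(20, 0.50), c(9, 11))
  expect_equal(valid_block_range(2, 0.60), c(1, 1))
  # valid blocks always contain both response types under the presets
  for (p in list(c(16, .80), c(16, .55), c(20, .75), c(20, .50))) {
    r <- valid_block_range(p[1], p[2])
    expect_gte(r[1], 1)
    expect_lte(r[2], p[1] - 1)
  }
})

test_that("block-validity ranges match the enumeration oracle", {
  # dyadic criteria (.25, .50, .75) are excluded: a symmetric binomial range
  # probability is a dyadic rational and can tie the criterion exactly,
  # where "strictly below" is knife-edge under floating point
  crits <- seq(0.05, 0.95, by = 0.05)
  crits <- crits[abs(crits * 4 - round(crits * 4)) > 1e-9]
  for (n in seq(2, 40, by = 2)) {
    for (crit in crits) {
      got <- valid_block_range(n, crit)
      want <- oracle_range(n, crit)
      expect_equal(got[1:2], want,
                   info = sprintf("n=%d crit=%.2f", n, crit))
      if (any(is.na(want))) expect_true(attr(got, "degenerate"))
    }
  }
})

test_that("partitioning blocks trials per staircase and flags validity", {
  cfg <- selection_config(16, 0.80)
  aw <- c(rep(c(0L, 1L), 8),            # block 0: 8 aware -> valid
          rep(0L, 11), rep(1L, 5),      # block 1: 5 aware -> invalid
          1L)                           # trailing partial block -> invalid
  tr <- make_trials(1, "detect", aw)
  out <- partition_and_flag(tr, cfg)
  expect_equal(out$block_index, rep(c(0L, 1L, 2L), c(16, 16, 1)))
  expect_equal(unique(out$block_valid[out$block_index == 0]), TRUE)
  expect_equal(unique(out$block_valid[out$block_index == 1]), FALSE)
  expect_equal(unique(out$block_valid[out$block_index == 2]), FALSE)

  # staircases are partitioned independently; catch trials stay unassigned
  tr2 <- rbind(make_trials(1, "detect", rep(c(0L, 1L), 8)),
               make_trials(1, "identify", rep(c(1L, 0L), 8)),
               make_trials(1, "catch", NA))
  tr2$trial_index <- seq_len(nrow(tr2)) - 1L
  out2 <- partition_and_flag(tr2, cfg)
  expect_true(all(out2$block_index[out2$staircase != "catch"] == 0L))
  expect_true(is.na(out2$block_index[out2$staircase == "catch"]))
})

test_that("opacity centering removes the block mean", {
  cfg <- selection_config(16, 0.80)
  tr <- make_trials(1, "detect", rep(c(0L, 1L), 8),
                    opacity = c(1, 2, 3, rep(2, 13)))
  tr <- center_opacity(partition_and_flag(tr, cfg))
  expect_equal(sum(tr$opacity_centered), 0)
  expect_equal(tr$opacity_centered[1:3],
               c(1, 2, 3) - mean(tr$opacity))
  # constant block centers to all zeros
  trc <- make_trials(2, "detect", rep(c(0L, 1L), 8), opacity = 3)
  trc <- center_opacity(partition_and_flag(trc, cfg))
  expect_true(all(trc$opacity_centered == 0))
})

test_that("centered opacity sums to zero per block on generated sessions", {
  set.seed(61)
  obs <- observer_params()
  ses <- run_session(obs, n_trials = 150)
  tr <- ses$trials
  tr$subject_id <- 1L
  tr$eeg_bad <- FALSE; tr$van_amp <- 0; tr$lp_amp <- 0
  tr$block_index <- NA_integer_; tr$block_valid <- NA
  tr$opacity_centered <- NA_real_
  tr <- center_opacity(partition_and_flag(tr, selection_config()))
  ok <- !is.na(tr$opacity_centered)
  sums <- tapply(tr$opacity_centered[ok],
                 interaction(tr$staircase[ok], tr$block_index[ok]),
                 sum)
  expect_true(all(abs(sums[!is.na(sums)]) < 1e-10))
})

test_that("minimum-cell rule drops conditions at the documented boundary", {
  cfg <- selection_config(16, 0.80, min_trials_per_cell = 25)
  # 48 detect trials, 24 aware / 24 unaware -> below 25 in both cells
  blk <- rep(c(0L, 1L), 8)
  t1 <- make_trials(1, "detect", rep(blk, 3))
  # 64 identify trials, 32/32 -> retained
  t2 <- make_trials(1, "identify", rep(blk, 4))
  tr <- rbind(t1, t2)
  tr$trial_index <- seq_len(nrow(tr)) - 1L
  tr <- center_opacity(partition_and_flag(tr, cfg))
  res <- apply_exclusions(tr, cfg)
  expect_equal(unique(res$retained$staircase), "identify")
  expect_equal(unname(res$report["n_below_min_cell"]), 48L)

  # exactly 25/25 in both cells is retained in full
  t25 <- make_trials(2, "detect", rep(blk, 4))[1:50, ]
  t25b <- make_trials(2, "identify", rep(blk, 4))[1:50, ]
  tr2 <- rbind(t25, t25b)
  tr2$trial_index <- seq_len(nrow(tr2)) - 1L
  tr2$block_valid <- TRUE; tr2$block_index <- 0L; tr2$opacity_centered <- 0
  res2 <- apply_exclusions(tr2, cfg)
  expect_equal(nrow(res2$retained), 100)
})

test_that("the 3-SD cut removes exactly the constructed outlier", {
  cfg <- selection_config(16, 0.80, min_trials_per_cell = 0)
  amps <- c(rep(0, 999), 100)
  tr <- make_trials(1, "detect", rep_len(c(0L, 1L), 1000),
                    van_amp = amps, lp_amp = 0)
  tr$block_valid <- TRUE; tr$block_index <- 0L; tr$opacity_centered <- 0
  res <- apply_exclusions(tr, cfg)
  # grand SD ~3.16, so the single value 100 deviates far beyond 3 SDs
  expect_equal(unname(res$report["n_van_outlier"]), 1L)
  expect_equal(unname(res$report["n_lp_outlier"]), 0L)
  expect_equal(nrow(res$van), 999)
  expect_false(any(res$van$van_amp == 100))
})

test_that("exclusion report reconciles at every stage", {
  set.seed(62)
  ds <- generate_dataset(n_subjects = 2, n_trials = 80, seed = 8)
  res <- select_trials(ds$trials, selection_config(min_trials_per_cell = 5))
  r <- res$report
  expect_equal(unname(r["n_input"] - r["n_invalid_block"] - r["n_bad_eeg"] -
                        r["n_below_min_cell"]),
               unname(r["n_retained"]))
  expect_equal(nrow(res$van), unname(r["n_retained"] - r["n_van_outlier"]))
  expect_equal(nrow(res$lp), unname(r["n_retained"] - r["n_lp_outlier"]))
  # valid blocks contain both aware and unaware trials
  counts <- tapply(res$retained$aware,
                   interaction(res$retained$subject_id,
                               res$retained$staircase,
                               res$retained$block_index, drop = TRUE),
                   function(a) min(mean(a), 1 - mean(a)))
  expect_true(all(counts > 0))
})

test_that("empty analysis sets are signalled explicitly", {
  cfg <- selection_config(16, 0.80, min_trials_per_cell = 100)
  tr <- make_trials(1, "detect", rep(c(0L, 1L), 8))
  tr$block_valid <- TRUE; tr$block_index <- 0L; tr$opacity_centered <- 0
  res <- apply_exclusions(tr, cfg)
  expect_true(res$empty)
  expect_equal(unname(res$report["n_retained"]), 0L)
})
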