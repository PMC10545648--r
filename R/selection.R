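#' Trial-selection configuration
#'
#' Settings for the at-threshold trial selection: block length, the binomial
#' chance criterion deciding whether a block's aware/unaware split is
#' consistent with a 50\% threshold, and the exclusion rules applied before
#' modelling. The named criterion presets reproduce the standard pairings
#' (block length 16: liberal .80, conservative .55; block length 20: liberal
#' .75, conservative .50).
#'
#' @param block_length Number of consecutive trials per block (even, >= 2;
#'   16 or 20 in the standard settings).
#' @param criterion Either a numeric cumulative-probability bound in (0, 1)
#'   or one of \code{"liberal"}, \code{"conservative"} (resolved via
#'   \code{block_length}).
#' @param min_trials_per_cell Minimum trials required in both the aware and
#'   the unaware cell of a subject-by-threshold condition (default 25;
#'   subjects below it lose that threshold condition).
#' @param amplitude_sd_cut Outlier cut in SD units on the trial amplitudes
#'   (default 3), applied separately for VAN and LP across all retained
#'   trials and subjects.
#' @param include_bad_eeg Keep trials flagged as bad during EEG screening?
#' @return An object of class \code{selection_config}.
#' @export
selection_config <- function(block_length = 16, criterion = "liberal",
                             min_trials_per_cell = 25, amplitude_sd_cut = 3,
                             include_bad_eeg = FALSE) {
  stopifnot(block_length >= 2, block_length %% 2 == 0)
  if (is.character(criterion)) {
    presets <- list(`16` = c(liberal = 0.80, conservative = 0.55),
                    `20` = c(liberal = 0.75, conservative = 0.50))
    pp <- presets[[as.character(block_length)]]
    if (is.null(pp) || !criterion %in% names(pp)) {
      stop("no ", criterion, " preset for block length ", block_length,
           "; give a numeric criterion", call. = FALSE)
    }
    criterion <- unname(pp[criterion])
  }
  stopifnot(criterion > 0, criterion < 1, min_trials_per_cell >= 0,
            amplitude_sd_cut > 0)
  structure(list(block_length = as.integer(block_length),
                 criterion = criterion,
                 min_trials_per_cell = min_trials_per_cell,
                 amplitude_sd_cut = amplitude_sd_cut,
                 include_bad_eeg = include_bad_eeg),
            class = "selection_config")
}

#' Chance-consistent range of aware counts in a block
#'
#' For a block of \code{n} trials at a true 50\% awareness threshold, the
#' aware count is Binomial(n, 0.5). The valid range is the widest symmetric
#' interval [n/2 - k, n/2 + k] whose exact binomial probability is still
#' strictly below \code{criterion}. Standard pairings: (16, .80) gives 6--10,
#' (16, .55) gives 7--9, (20, .75) gives 8--12, (20, .50) gives 9--11.
#'
#' @param n Even block length.
#' @param criterion Cumulative-probability bound in (0, 1).
#' @return Integer vector \code{c(lo, hi)}. If even the central count alone
#'   has probability >= criterion the range is degenerate:
#'   \code{c(NA, NA)} with attribute \code{degenerate = TRUE}.
#' @export
valid_block_range <- function(n, criterion) {
  stopifnot(n %% 2 == 0, n >= 2, criterion > 0, criterion < 1)
  half <- n / 2
  k <- -1L
  repeat {
    kk <- k + 1L
    if (half - kk < 0) break
    p <- stats::pbinom(half + kk, n, 0.5) -
      stats::pbinom(half - kk - 1, n, 0.5)
    if (p < criterion) k <- kk else break
  }
  if (k < 0L) {
    return(structure(c(NA_integer_, NA_integer_), degenerate = TRUE))
  }
  c(half - k, half + k)
}

#' Partition staircase trials into blocks and flag valid blocks
#'
#' Consecutive non-catch trials of each subject-by-staircase stream are
#' grouped, in trial order, into blocks of \code{block_length}. A trailing
#' partial block is flagged invalid. A full block is valid when its aware
#' count falls inside \code{\link{valid_block_range}}. Catch trials keep
#' \code{NA} block assignments.
#'
#' @param trials Trial data frame (rows ordered by trial within subject).
#' @param cfg A \code{\link{selection_config}}.
#' @return The trial table with \code{block_index} (0-based within each
#'   subject-by-staircase stream) and \code{block_valid} filled in.
#' @export
partition_and_flag <- function(trials, cfg) {
  rng <- valid_block_range(cfg$block_length, cfg$criterion)
  if (isTRUE(attr(rng, "degenerate"))) {
    stop("degenerate chance criterion: no block can be valid", call. = FALSE)
  }
  trials$block_index <- NA_integer_
  trials$block_valid <- NA
  noncatch <- trials$staircase != "catch"
  key <- interaction(trials$subject_id, trials$staircase, drop = TRUE)
  for (g in split(which(noncatch), key[noncatch], drop = TRUE)) {
    g <- g[order(trials$trial_index[g])]
    bi <- (seq_along(g) - 1L) %/% cfg$block_length
    trials$block_index[g] <- bi
    for (b in unique(bi)) {
      idx <- g[bi == b]
      if (length(idx) < cfg$block_length) {
        trials$block_valid[idx] <- FALSE
      } else {
        n_aware <- sum(trials$aware[idx])
        trials$block_valid[idx] <- n_aware >= rng[1] && n_aware <= rng[2]
      }
    }
  }
  trials
}

#' Mean-center opacity within valid blocks
#'
#' Within each valid block, subtracts the block mean opacity so that only
#' relative within-block opacity differences enter the models (removing slow
#' drift of the staircase level). Centered values sum to zero per block;
#' trials outside valid blocks keep \code{NA}.
#'
#' @param trials Trial table with \code{block_index}/\code{block_valid} set
#'   (see \code{\link{partition_and_flag}}).
#' @return The trial table with \code{opacity_centered} filled in.
#' @export
center_opacity <- function(trials) {
  if (all(is.na(trials$block_index))) {
    stop("block_index not assigned; run partition_and_flag() first",
         call. = FALSE)
  }
  trials$opacity_centered <- NA_real_
  sel <- which(!is.na(trials$block_valid) & trials$block_valid)
  key <- interaction(trials$subject_id[sel], trials$staircase[sel],
                     trials$block_index[sel], drop = TRUE)
  for (idx in split(sel, key, drop = TRUE)) {
    trials$opacity_centered[idx] <-
      trials$opacity[idx] - mean(trials$opacity[idx])
  }
  trials
}

#' Apply the exclusion rules and build the analysis sets
#'
#' Starting from the blocked trial table, this applies in order: (1) keep
#' only trials in valid blocks; (2) unless \code{include_bad_eeg}, drop
#' trials flagged bad during EEG screening; (3) per subject and threshold
#' condition, drop the condition when fewer than \code{min_trials_per_cell}
#' trials remain in either the aware or the unaware cell (a subject failing
#' both conditions is excluded entirely); (4) in a single pass, flag trials
#' whose VAN (respectively LP) amplitude deviates more than
#' \code{amplitude_sd_cut} SDs from the grand mean over all retained trials
#' and subjects, separately per measure.
#'
#' @param trials Trial table after \code{\link{partition_and_flag}} and
#'   \code{\link{center_opacity}}.
#' @param cfg A \code{\link{selection_config}}.
#' @return A list: \code{van} and \code{lp} (analysis data frames for the two
#'   measures), \code{retained} (trials surviving steps 1--3, with outlier
#'   flags), and \code{report} (counts at every stage; input equals retained
#'   plus dropped at each stage).
#' @export
apply_exclusions <- function(trials, cfg) {
  n_input <- nrow(trials)
  keep <- !is.na(trials$block_valid) & trials$block_valid
  n_invalid <- n_input - sum(keep)
  tr <- trials[keep, , drop = FALSE]
  if (!cfg$include_bad_eeg) {
    n_bad <- sum(tr$eeg_bad)
    tr <- tr[!tr$eeg_bad, , drop = FALSE]
  } else {
    n_bad <- 0L
  }
  # minimum trials per aware/unaware cell, per subject x threshold
  drop_cell <- rep(FALSE, nrow(tr))
  for (s in unique(tr$subject_id)) {
    for (thr in c("detect", "identify")) {
      idx <- which(tr$subject_id == s & tr$staircase == thr)
      n_aw <- sum(tr$aware[idx] == 1L)
      n_un <- sum(tr$aware[idx] == 0L)
      if (min(n_aw, n_un) < cfg$min_trials_per_cell) drop_cell[idx] <- TRUE
    }
  }
  n_cell <- sum(drop_cell)
  tr <- tr[!drop_cell, , drop = FALSE]
  if (nrow(tr) == 0) {
    return(structure(list(van = tr, lp = tr, retained = tr,
                          report = c(n_input = n_input,
                                     n_invalid_block = n_invalid,
                                     n_bad_eeg = n_bad,
                                     n_below_min_cell = n_cell,
                                     n_retained = 0L,
                                     n_van_outlier = 0L, n_lp_outlier = 0L),
                          empty = TRUE),
                     class = "selection_result"))
  }
  cut <- cfg$amplitude_sd_cut
  van_out <- abs(tr$van_amp - mean(tr$van_amp)) > cut * stats::sd(tr$van_amp)
  lp_out <- abs(tr$lp_amp - mean(tr$lp_amp)) > cut * stats::sd(tr$lp_amp)
  tr$van_outlier <- van_out
  tr$lp_outlier <- lp_out
  structure(list(van = tr[!van_out, , drop = FALSE],
                 lp = tr[!lp_out, , drop = FALSE],
                 retained = tr,
                 report = c(n_input = n_input, n_invalid_block = n_invalid,
                            n_bad_eeg = n_bad, n_below_min_cell = n_cell,
                            n_retained = nrow(tr),
                            n_van_outlier = sum(van_out),
                            n_lp_outlier = sum(lp_out)),
                 empty = FALSE),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("At-threshold trial selection\n")
  r <- x$report
  cat(sprintf("  input %d | invalid blocks -%d | bad EEG -%d | min-cell -%d -> retained %d\n",
              r["n_input"], r["n_invalid_block"], r["n_bad_eeg"],
              r["n_below_min_cell"], r["n_retained"]))
  cat(sprintf("  amplitude outliers: VAN %d, LP %d\n",
              r["n_van_outlier"], r["n_lp_outlier"]))
  invisible(x)
}

#' Run the full selection stage
#'
#' Convenience wrapper: partition into blocks, flag valid blocks, center
#' opacity, and apply the exclusion rules.
#'
#' @inheritParams apply_exclusions
#' @return A \code{selection_result}, see \code{\link{apply_exclusions}}.
#' @export
select_trials <- function(trials, cfg = selection_config()) {
  trials <- partition_and_flag(trials, cfg)
  trials <- center_opacity(trials)
  apply_exclusions(trials, cfg)
}
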