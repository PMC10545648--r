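#' The 16-setting multiverse grid
#'
#' Full factorial grid over the four analysis settings that are varied:
#' block length (16 or 20), chance criterion (liberal or conservative, with
#' the standard pairing per block length), inclusion of trials flagged bad
#' during EEG screening, and inclusion of grating orientation as an
#' additional model predictor. Cell 1 (16, liberal, exclude bad, no
#' orientation) is the main analysis.
#'
#' @return A 16-row data frame with a \code{cell} index and the four
#'   settings.
#' @export
multiverse_grid <- function() {
  g <- expand.grid(block_length = c(16L, 20L),
                   criterion = c("liberal", "conservative"),
                   include_bad_eeg = c(FALSE, TRUE),
                   include_orientation = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  cbind(cell = seq_len(nrow(g)), g)
}

#' Deterministic per-cell seed
#'
#' @param seed Base seed of the multiverse run.
#' @param cell Cell index (1--16).
#' @return The integer seed used for that cell's model fits.
#' @export
multiverse_cell_seed <- function(seed, cell) {
  as.integer(seed) + as.integer(cell)
}

#' Run the multiverse analysis
#'
#' Re-runs the selection and the full-interaction amplitude models under all
#' 16 analysis settings and collects, per cell and outcome, the detection
#' awareness effect, the identification awareness effect, and their
#' difference (interaction), each with a 95\% credible interval. A cell
#' whose analysis set is empty (or whose fit fails) is marked failed and the
#' run continues. Per-cell seeds are derived deterministically from the base
#' seed, so the grid's execution order is irrelevant and the main cell
#' reproduces a standalone fit with \code{multiverse_cell_seed(seed, 1)}
#' exactly.
#'
#' @param trials Blocked-stage input: the raw trial table of a dataset
#'   (selection is re-run per cell).
#' @param outcomes Outcome columns to model.
#' @param seed Base seed.
#' @param fast Logical; fast mode uses fewer posterior draws per cell
#'   (400 kept after 200 warmup, 2 chains) than full mode (1000 after 500).
#' @param chains,iter,warmup Optional explicit MCMC settings overriding the
#'   mode defaults.
#' @param min_trials_per_cell,amplitude_sd_cut Selection settings held fixed
#'   across the grid.
#' @return A long-format data frame of class \code{multiverse_result}: one
#'   row per cell x outcome x effect with posterior mean and CI, the cell
#'   settings, and a \code{failed} flag.
#' @export
run_multiverse <- function(trials, outcomes = c("van_amp", "lp_amp"),
                           seed = 1, fast = TRUE,
                           chains = 2, iter = NULL, warmup = NULL,
                           min_trials_per_cell = 25, amplitude_sd_cut = 3) {
  if (inherits(trials, "awareness_dataset")) trials <- trials$trials
  if (is.null(iter)) iter <- if (fast) 400 else 1000
  if (is.null(warmup)) warmup <- if (fast) 200 else 500
  grid <- multiverse_grid()
  rows <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    cellcfg <- grid[ci, ]
    cell_seed <- multiverse_cell_seed(seed, cellcfg$cell)
    res <- tryCatch({
      cfg <- selection_config(block_length = cellcfg$block_length,
                              criterion = cellcfg$criterion,
                              min_trials_per_cell = min_trials_per_cell,
                              amplitude_sd_cut = amplitude_sd_cut,
                              include_bad_eeg = cellcfg$include_bad_eeg)
      sel <- select_trials(trials, cfg)
      if (isTRUE(sel$empty)) stop("empty analysis set")
      do.call(rbind, lapply(outcomes, function(oc) {
        dat <- if (oc == "lp_amp") sel$lp else sel$van
        fit <- fit_awareness_model(dat, outcome = oc,
                                   formula = "full_interaction",
                                   include_orientation =
                                     cellcfg$include_orientation,
                                   chains = chains, iter = iter,
                                   warmup = warmup, seed = cell_seed)
        eff <- awareness_effects(fit)
        do.call(rbind, lapply(names(eff), function(en) {
          d <- eff[[en]]
          data.frame(cellcfg, outcome = oc, effect = en,
                     mean = mean(d),
                     ci_low = unname(stats::quantile(d, 0.025)),
                     ci_high = unname(stats::quantile(d, 0.975)),
                     n_trials = fit$n_obs, n_subjects = fit$n_subjects,
                     failed = FALSE, row.names = NULL)
        }))
      }))
    }, error = function(e) {
      do.call(rbind, lapply(outcomes, function(oc) {
        data.frame(cellcfg, outcome = oc,
                   effect = c("detect", "identify", "interaction"),
                   mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   n_trials = NA_integer_, n_subjects = NA_integer_,
                   failed = TRUE, row.names = NULL)
      }))
    })
    rows[[ci]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("multiverse_result", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Summarize robustness across multiverse cells
#'
#' Per outcome and effect, counts the successful cells whose posterior mean
#' shares the main cell's sign, the cells whose 95\% CI excludes zero, and
#' the cells whose CI overlaps the main cell's CI, together with the range
#' of estimates.
#'
#' @param cells A \code{\link{run_multiverse}} result.
#' @return A data frame with one row per outcome x effect.
#' @export
summarize_robustness <- function(cells) {
  ok <- cells[!cells$failed, , drop = FALSE]
  if (nrow(ok) == 0) stop("no successful multiverse cells", call. = FALSE)
  combos <- unique(ok[, c("outcome", "effect")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- ok[ok$outcome == combos$outcome[i] &
                ok$effect == combos$effect[i], , drop = FALSE]
    main <- sub[sub$cell == 1, , drop = FALSE]
    ref_sign <- if (nrow(main) == 1) sign(main$mean) else
      sign(stats::median(sub$mean))
    overlap <- if (nrow(main) == 1) {
      sum(sub$ci_low <= main$ci_high & sub$ci_high >= main$ci_low)
    } else {
      NA_integer_
    }
    data.frame(outcome = combos$outcome[i], effect = combos$effect[i],
               n_cells = nrow(sub),
               sign_consistent = sum(sign(sub$mean) == ref_sign),
               ci_excludes_zero = sum(sub$ci_low > 0 | sub$ci_high < 0),
               ci_overlaps_main = overlap,
               min_estimate = min(sub$mean), max_estimate = max(sub$mean),
               row.names = NULL)
  }))
  out
}

#' @export
print.multiverse_result <- function(x, ...) {
  cat(sprintf("Multiverse analysis: %d cells, %d failed\n",
              length(unique(x$cell)),
              length(unique(x$cell[x$failed]))))
  print(summarize_robustness(x), row.names = FALSE)
  invisible(x)
}
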