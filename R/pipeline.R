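#' Run configuration for the analysis pipeline
#'
#' Bundles every setting of a reproducible run: the seed, dataset-generation
#' parameters, trial-selection settings, model settings, and whether the
#' multiverse is run. The configuration is fully serializable; writers place
#' it alongside the outputs.
#'
#' @param seed Integer master seed; every random stream of the run derives
#'   from it.
#' @param n_subjects,n_trials Dataset size.
#' @param selection A \code{\link{selection_config}}.
#' @param prior_scale Prior SD for the regression models.
#' @param likelihood Observation model for the amplitude regressions.
#' @param fast Logical; fast mode uses reduced posterior draws.
#' @param multiverse Run the 16-cell multiverse as part of the pipeline?
#' @param behavior Fit the logistic accuracy models (requires rjags)?
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(seed = 1, n_subjects = 38, n_trials = 500,
                       selection = selection_config(),
                       prior_scale = 2, likelihood = "student_t",
                       fast = FALSE, multiverse = FALSE, behavior = TRUE) {
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 n_trials = n_trials, selection = selection,
                 prior_scale = prior_scale, likelihood = likelihood,
                 fast = fast, multiverse = multiverse, behavior = behavior),
            class = "run_config")
}

#' Run the full awareness analysis pipeline
#'
#' Orchestrates selection, feature-based exclusion, the detection-only and
#' full-interaction robust amplitude models for VAN and LP, the logistic
#' accuracy models, and (optionally) the multiverse. Per-stage seeds derive
#' deterministically from the configuration seed, so a run is exactly
#' reproducible.
#'
#' @param dataset An \code{\link{generate_dataset}} result, or a raw trial
#'   table with the standard columns.
#' @param config A \code{\link{run_config}}.
#' @return An object of class \code{awareness_pipeline}: the selection
#'   result, fitted models and their summaries, derived awareness effects,
#'   the behaviour fits, and (if requested) the multiverse table and its
#'   robustness summary.
#' @export
run_awareness_pipeline <- function(dataset, config = run_config()) {
  trials <- if (inherits(dataset, "awareness_dataset")) dataset$trials else
    dataset
  sel <- select_trials(trials, config$selection)
  if (isTRUE(sel$empty)) stop("empty analysis set after exclusions",
                              call. = FALSE)
  iter <- if (config$fast) 400 else 1000
  warmup <- if (config$fast) 200 else 500
  fits <- list()
  seeds <- config$seed + c(van_detection = 0L, van_full = 1L,
                           lp_detection = 2L, lp_full = 3L)
  for (oc in c("van_amp", "lp_amp")) {
    dat <- if (oc == "lp_amp") sel$lp else sel$van
    tag <- if (oc == "lp_amp") "lp" else "van"
    fits[[paste0(tag, "_detection")]] <-
      fit_awareness_model(dat, oc, "detection_only",
                          prior_scale = config$prior_scale,
                          likelihood = config$likelihood,
                          iter = iter, warmup = warmup,
                          seed = seeds[[paste0(tag, "_detection")]])
    fits[[paste0(tag, "_full")]] <-
      fit_awareness_model(dat, oc, "full_interaction",
                          prior_scale = config$prior_scale,
                          likelihood = config$likelihood,
                          iter = iter, warmup = warmup,
                          seed = seeds[[paste0(tag, "_full")]])
  }
  behavior <- NULL
  if (isTRUE(config$behavior) && requireNamespace("rjags", quietly = TRUE)) {
    behavior <- list(
      detection = fit_behavior_model(sel$retained, "detection_only",
                                     prior_scale = config$prior_scale,
                                     iter = iter, warmup = warmup,
                                     seed = config$seed + 50L),
      full = fit_behavior_model(sel$retained, "full_interaction",
                                prior_scale = config$prior_scale,
                                iter = iter, warmup = warmup,
                                seed = config$seed + 51L))
  }
  mv <- NULL
  if (isTRUE(config$multiverse)) {
    mv <- run_multiverse(trials, seed = config$seed, fast = config$fast)
  }
  structure(list(config = config, selection = sel, fits = fits,
                 summaries = lapply(fits, summary),
                 effects = lapply(fits[c("van_full", "lp_full")],
                                  function(f) {
                                    lapply(awareness_effects(f), function(d) {
                                      c(mean = mean(d),
                                        ci_low = unname(stats::quantile(d, 0.025)),
                                        ci_high = unname(stats::quantile(d, 0.975)),
                                        bf10 = as.numeric(
                                          savage_dickey_bf(d, config$prior_scale)),
                                        pd = probability_of_direction(d),
                                        rope = rope_fraction(d))
                                    })
                                  }),
                 behavior = behavior, multiverse = mv,
                 robustness = if (!is.null(mv)) summarize_robustness(mv)),
            class = "awareness_pipeline")
}

#' @export
print.awareness_pipeline <- function(x, ...) {
  cat("Threshold-tracked awareness analysis\n")
  r <- x$selection$report
  cat(sprintf("  analysis set: %d trials retained of %d\n",
              r["n_retained"], r["n_input"]))
  for (m in c("van_full", "lp_full")) {
    eff <- x$effects[[m]]
    lab <- if (m == "van_full") "VAN" else "LP"
    cat(sprintf("  %s: detect %+.2f [%+.2f, %+.2f], identify %+.2f [%+.2f, %+.2f], interaction %+.2f (BF10 %.3g)\n",
                lab, eff$detect["mean"], eff$detect["ci_low"],
                eff$detect["ci_high"], eff$identify["mean"],
                eff$identify["ci_low"], eff$identify["ci_high"],
                eff$interaction["mean"], eff$interaction["bf10"]))
  }
  if (!is.null(x$behavior) && !isTRUE(x$behavior$full$separation)) {
    cat("  accuracy:",
        paste(sprintf("%s %.2f", names(x$behavior$full$proportions),
                      x$behavior$full$proportions), collapse = ", "), "\n")
  }
  if (!is.null(x$robustness)) {
    cat("  multiverse robustness:\n")
    print(x$robustness, row.names = FALSE)
  }
  invisible(x)
}

#' Write pipeline summaries to JSON
#'
#' Serializes the run configuration, the exclusion report, the per-model
#' coefficient summaries and derived awareness effects (and, when present,
#' behaviour proportions and the multiverse robustness table).
#'
#' @param pipeline An \code{\link{run_awareness_pipeline}} result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(pipeline, path) {
  out <- list(
    config = unclass_rec(pipeline$config),
    exclusion_report = as.list(pipeline$selection$report),
    models = lapply(pipeline$summaries, as.data.frame),
    effects = lapply(pipeline$effects, function(m) lapply(m, as.list)),
    behavior = if (!is.null(pipeline$behavior)) {
      lapply(pipeline$behavior, function(b) {
        if (isTRUE(b$separation)) list(separation = TRUE) else
          list(proportions = as.list(b$proportions),
               bf10_awareness = b$bf10_awareness)
      })
    },
    robustness = pipeline$robustness)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

unclass_rec <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_rec) else x
}

#' Render a plain-text report of a pipeline run
#'
#' @param pipeline An \code{\link{run_awareness_pipeline}} result.
#' @param path Optional file to write to.
#' @return The report lines, invisibly when written to a file.
#' @export
report_pipeline <- function(pipeline, path = NULL) {
  lines <- utils::capture.output(print(pipeline))
  failed <- pipeline$multiverse$failed
  if (!is.null(failed) && any(failed)) {
    lines <- c(lines, sprintf("NOTE: %d multiverse cell(s) failed",
                              length(unique(pipeline$multiverse$cell[failed]))))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
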