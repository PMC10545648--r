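#' Simulated observer parameters
#'
#' Defines a simulated observer with two probit psychometric functions on the
#' opacity scale (0--100): one for detection awareness (reporting at least
#' "something", PAS >= 2) and one for identification awareness (reporting
#' "clear orientation", PAS = 3). The observer optionally false-alarms at zero
#' opacity and lapses (responds uniformly at random) on a small fraction of
#' trials. Orientation-report accuracy is governed by a condition-by-rating
#' probability table.
#'
#' @param mu_detect Opacity at which P(PAS >= 2) = 0.5 (detection threshold).
#' @param sigma_detect Probit slope scale of the detection function, in
#'   opacity units.
#' @param mu_identify Opacity at which P(PAS = 3) = 0.5 (identification
#'   threshold). Must exceed \code{mu_detect}.
#' @param sigma_identify Probit slope scale of the identification function.
#' @param false_alarm_rate Probability of reporting PAS >= 2 at opacity 0.
#' @param lapse_rate Probability that a rating is drawn uniformly from
#'   \{1, 2, 3\} irrespective of opacity.
#' @param correct_prob Named numeric vector mapping
#'   \code{"<staircase>.PAS<k>"} to the probability of a correct orientation
#'   report. Defaults follow the condition-wise accuracies the design targets:
#'   near chance below the detection threshold and near ceiling for clearly
#'   identified stimuli.
#' @return An object of class \code{observer_params}.
#' @examples
#' obs <- observer_params()
#' observer_respond(obs, "detect", opacity = obs$mu_detect)
#' @export
observer_params <- function(mu_detect = 1.05, sigma_detect = 0.30,
                            mu_identify = 2.85, sigma_identify = 0.45,
                            false_alarm_rate = 0.04, lapse_rate = 0.02,
                            correct_prob = c(detect.PAS1 = 0.51,
                                             detect.PAS2 = 0.53,
                                             detect.PAS3 = 0.97,
                                             identify.PAS1 = 0.51,
                                             identify.PAS2 = 0.72,
                                             identify.PAS3 = 0.97)) {
  stopifnot(mu_identify > mu_detect,
            sigma_detect > 0, sigma_identify > 0,
            false_alarm_rate >= 0, false_alarm_rate <= 0.2,
            lapse_rate >= 0, lapse_rate <= 0.2,
            all(correct_prob >= 0), all(correct_prob <= 1))
  structure(list(mu_detect = mu_detect, sigma_detect = sigma_detect,
                 mu_identify = mu_identify, sigma_identify = sigma_identify,
                 false_alarm_rate = false_alarm_rate, lapse_rate = lapse_rate,
                 correct_prob = correct_prob),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Simulated observer (two-probit ordered response model)\n")
  cat(sprintf("  detection threshold:      mu = %.3f, sigma = %.3f\n",
              x$mu_detect, x$sigma_detect))
  cat(sprintf("  identification threshold: mu = %.3f, sigma = %.3f\n",
              x$mu_identify, x$sigma_identify))
  cat(sprintf("  false-alarm rate %.3f, lapse rate %.3f\n",
              x$false_alarm_rate, x$lapse_rate))
  invisible(x)
}

#' Response-category probabilities at a given opacity
#'
#' Closed-form probabilities of the three PAS ratings under the two-probit
#' ordered model, before the lapse mixture is applied:
#' P(PAS >= 2) = fa + (1 - fa) * Phi((x - mu_d)/sigma_d) and
#' P(PAS = 3) = min(P(PAS >= 2), Phi((x - mu_i)/sigma_i)), which enforces the
#' ordered-response coherence P(PAS = 3) <= P(PAS >= 2).
#'
#' @param obs An \code{\link{observer_params}} object.
#' @param opacity Opacity value(s) in [0, 100].
#' @return A matrix with columns \code{p1}, \code{p2}, \code{p3} summing to 1.
#' @export
pas_probabilities <- function(obs, opacity) {
  if (any(opacity < 0 | opacity > 100)) {
    stop("opacity must lie in [0, 100]", call. = FALSE)
  }
  p_ge2 <- obs$false_alarm_rate +
    (1 - obs$false_alarm_rate) *
      stats::pnorm((opacity - obs$mu_detect) / obs$sigma_detect)
  p3 <- pmin(p_ge2, stats::pnorm((opacity - obs$mu_identify) / obs$sigma_identify))
  cbind(p1 = 1 - p_ge2, p2 = p_ge2 - p3, p3 = p3)
}

#' Draw a PAS rating from a simulated observer
#'
#' With probability \code{lapse_rate} the rating is uniform on \{1, 2, 3\};
#' otherwise it is drawn from the two-probit category probabilities
#' (\code{\link{pas_probabilities}}). Catch trials (opacity 0) produce false
#' alarms at the observer's \code{false_alarm_rate}.
#'
#' @inheritParams pas_probabilities
#' @param staircase One of \code{"detect"}, \code{"identify"}, \code{"catch"}.
#'   The rating model is the same for all; the argument is carried so callers
#'   can route trials without special-casing.
#' @return An integer rating in \{1, 2, 3\}.
#' @export
observer_respond <- function(obs, staircase = c("detect", "identify", "catch"),
                             opacity) {
  staircase <- match.arg(staircase)
  if (length(opacity) != 1 || !is.finite(opacity) || opacity < 0 || opacity > 100) {
    stop("opacity must be a single value in [0, 100]", call. = FALSE)
  }
  if (obs$lapse_rate > 0 && stats::runif(1) < obs$lapse_rate) {
    return(sample.int(3L, 1L))
  }
  p <- pas_probabilities(obs, opacity)[1L, ]
  sample.int(3L, 1L, prob = p)
}

#' Simulate an orientation report
#'
#' The report is correct with the probability stored in the observer's
#' correctness table for the (staircase, rating) cell; otherwise the opposite
#' orientation is reported.
#'
#' @inheritParams observer_respond
#' @param pas The PAS rating given on the trial.
#' @param true_orientation \code{"left"} or \code{"right"}.
#' @return A list with \code{orientation} (the reported side) and
#'   \code{correct} (0/1).
#' @export
observer_report_orientation <- function(obs,
                                        staircase = c("detect", "identify"),
                                        pas, true_orientation) {
  staircase <- match.arg(staircase)
  stopifnot(pas %in% 1:3, true_orientation %in% c("left", "right"))
  key <- sprintf("%s.PAS%d", staircase, pas)
  p <- obs$correct_prob[key]
  if (is.na(p)) {
    stop("no correctness probability configured for ", key, call. = FALSE)
  }
  correct <- as.integer(stats::runif(1) < p)
  reported <- if (correct == 1L) true_orientation else
    setdiff(c("left", "right"), true_orientation)
  list(orientation = reported, correct = correct)
}

#' Derive the awareness dummy from a staircase and PAS rating
#'
#' Detection-threshold trials count PAS >= 2 as aware; identification-threshold
#' trials count PAS = 3 as aware. Catch trials have no awareness dummy.
#'
#' @param staircase Character vector of staircase labels.
#' @param pas Integer vector of PAS ratings.
#' @return Integer vector of 0/1 (NA for catch trials).
#' @export
aware_from_pas <- function(staircase, pas) {
  out <- ifelse(staircase == "detect", as.integer(pas >= 2L),
         ifelse(staircase == "identify", as.integer(pas == 3L), NA_integer_))
  as.integer(out)
}
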