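#' Staircase configuration
#'
#' Settings for an adaptive up-down opacity staircase. Opacity lives on a
#' 0--100 scale but the underlying software grid has \code{resolution}
#' representable levels on [0, 1], so the grid spacing is
#' \code{100 / resolution} opacity units. The step size is multiplied by
#' \code{step_shrink_factor} after every second reversal and never drops below
#' \code{min_step} (one grid unit by default).
#'
#' @param rule \code{"one_up_one_down"} (move after every response) or
#'   \code{"two_up_two_down"} (move only after two consecutive identical
#'   responses). Both variants converge on the 50\% point of the psychometric
#'   function.
#' @param initial_opacity Starting opacity (0--100).
#' @param initial_step Initial step size in opacity units.
#' @param step_shrink_factor Multiplier in (0, 1] applied to the step after
#'   every second reversal.
#' @param min_step Smallest allowed step; defaults to one grid unit.
#' @param resolution Number of representable opacity levels on the [0, 1]
#'   software scale (>= 2).
#' @param bounds Two-element numeric, the admissible opacity range.
#' @return An object of class \code{staircase_config}.
#' @export
staircase_config <- function(rule = c("two_up_two_down", "one_up_one_down"),
                             initial_opacity = 5, initial_step = 1,
                             step_shrink_factor = 0.5,
                             min_step = NULL, resolution = 500,
                             bounds = c(0, 100)) {
  rule <- match.arg(rule)
  stopifnot(step_shrink_factor > 0, step_shrink_factor <= 1,
            resolution >= 2, length(bounds) == 2, bounds[1] < bounds[2],
            initial_opacity >= bounds[1], initial_opacity <= bounds[2],
            initial_step > 0)
  grid_unit <- 100 / resolution
  if (is.null(min_step)) min_step <- grid_unit
  structure(list(rule = rule, initial_opacity = initial_opacity,
                 initial_step = initial_step,
                 step_shrink_factor = step_shrink_factor,
                 min_step = min_step, resolution = resolution,
                 grid_unit = grid_unit, bounds = bounds),
            class = "staircase_config")
}

#' Initial staircase state
#'
#' @param cfg A \code{\link{staircase_config}}.
#' @return An object of class \code{staircase_state} with the current opacity
#'   (snapped to the grid), current step, reversal count, movement direction,
#'   consecutive-response counter and response history.
#' @export
staircase_init <- function(cfg) {
  structure(list(opacity = snap_to_grid(cfg$initial_opacity, cfg),
                 step = cfg$initial_step,
                 n_reversals = 0L,
                 last_direction = "none",
                 consecutive_same = 0L,
                 last_response = NA_integer_,
                 history = list(opacity = numeric(0), aware = integer(0))),
            class = "staircase_state")
}

# Snap an opacity value to the representable grid. Exact half-grid ties are
# rounded against the current direction of movement so the staircase cannot
# lock into an oscillation between two adjacent levels.
snap_to_grid <- function(x, cfg, direction = "none") {
  g <- cfg$grid_unit
  q <- x / g
  frac <- q - floor(q)
  k <- if (abs(frac - 0.5) < 1e-9) {
    switch(direction,
           down = ceiling(q),   # moving down: tie resolves upward (against)
           up   = floor(q),     # moving up: tie resolves downward (against)
           round(q))
  } else {
    round(q)
  }
  min(max(k * g, cfg$bounds[1]), cfg$bounds[2])
}

#' Advance a staircase by one response
#'
#' Implements the transformed up-down update. Under the 1-up-1-down rule an
#' unaware response raises opacity by the current step and an aware response
#' lowers it. Under the 2-up-2-down rule a move occurs only after two
#' consecutive identical responses, and the consecutive-response counter
#' resets after each move. A change of movement direction counts as a
#' reversal; after every second reversal the step is multiplied by the shrink
#' factor (never below \code{min_step}). The new opacity is clamped to the
#' bounds and snapped to the resolution grid.
#'
#' @param state A \code{\link{staircase_init}} state.
#' @param cfg The staircase configuration.
#' @param aware 0/1 response on this trial.
#' @return The updated \code{staircase_state}.
#' @export
staircase_update <- function(state, cfg, aware) {
  stopifnot(aware %in% c(0L, 1L))
  aware <- as.integer(aware)
  state$history$opacity <- c(state$history$opacity, state$opacity)
  state$history$aware <- c(state$history$aware, aware)
  move <- 0L
  if (cfg$rule == "one_up_one_down") {
    move <- if (aware == 1L) -1L else 1L
  } else {
    if (!is.na(state$last_response) && state$last_response == aware) {
      state$consecutive_same <- state$consecutive_same + 1L
    } else {
      state$consecutive_same <- 1L
    }
    state$last_response <- aware
    if (state$consecutive_same >= 2L) {
      move <- if (aware == 1L) -1L else 1L
      state$consecutive_same <- 0L
      state$last_response <- NA_integer_
    }
  }
  if (move != 0L) {
    direction <- if (move > 0L) "up" else "down"
    if (state$last_direction != "none" && direction != state$last_direction) {
      state$n_reversals <- state$n_reversals + 1L
      if (state$n_reversals %% 2L == 0L) {
        state$step <- max(cfg$min_step, state$step * cfg$step_shrink_factor)
      }
    }
    state$last_direction <- direction
    state$opacity <- snap_to_grid(state$opacity + move * state$step,
                                  cfg, direction)
  }
  state
}

#' Run an interleaved staircase session for one observer
#'
#' Simulates a full session in which a detection staircase and an
#' identification staircase are interleaved, with stimulus-absent catch trials
#' mixed in. Two trial-scheduling modes are available: \code{"bernoulli"}
#' draws each trial type independently (catch with probability
#' \code{catch_prob}, otherwise either staircase with equal probability and a
#' random left/right orientation), and \code{"sections"} schedules
#' pseudo-random sections of 21 trials (10 left, 10 right, 1 catch; staircase
#' assignment balanced within section), mirroring a fixed-count design.
#'
#' @param observer An \code{\link{observer_params}} object.
#' @param detect_cfg,identify_cfg \code{\link{staircase_config}}s for the two
#'   staircases.
#' @param n_trials Total number of trials (>= 1).
#' @param catch_prob Probability of a catch trial (Bernoulli mode).
#' @param mode Trial scheduling mode, see above.
#' @return A list with \code{trials} (a data frame with one row per trial:
#'   trial_index, staircase, opacity, orientation, pas, aware, threshold_dummy,
#'   correct) and the two final staircase states
#'   (\code{detect_state}, \code{identify_state}).
#' @export
run_session <- function(observer, detect_cfg = staircase_config(),
                        identify_cfg = staircase_config(initial_opacity = 8),
                        n_trials = 500, catch_prob = 0.05,
                        mode = c("bernoulli", "sections")) {
  mode <- match.arg(mode)
  stopifnot(n_trials >= 1)
  sched <- if (mode == "bernoulli") {
    is_catch <- stats::runif(n_trials) < catch_prob
    data.frame(
      staircase = ifelse(is_catch, "catch",
                         ifelse(stats::runif(n_trials) < 0.5,
                                "detect", "identify")),
      orientation = ifelse(is_catch, "none",
                           ifelse(stats::runif(n_trials) < 0.5,
                                  "left", "right")))
  } else {
    section <- data.frame(
      staircase = c(rep(c("detect", "identify"), each = 10), "catch"),
      orientation = c(rep(c("left", "right"), 10), "none"))
    n_sections <- ceiling(n_trials / 21)
    out <- do.call(rbind, lapply(seq_len(n_sections), function(i) {
      section[sample.int(21L), , drop = FALSE]
    }))
    out[seq_len(n_trials), , drop = FALSE]
  }
  states <- list(detect = staircase_init(detect_cfg),
                 identify = staircase_init(identify_cfg))
  cfgs <- list(detect = detect_cfg, identify = identify_cfg)
  n <- nrow(sched)
  opacity <- numeric(n); pas <- integer(n); aware <- integer(n)
  correct <- integer(n)
  for (i in seq_len(n)) {
    sc <- sched$staircase[i]
    if (sc == "catch") {
      opacity[i] <- 0
      pas[i] <- observer_respond(observer, "catch", 0)
      aware[i] <- NA_integer_
      correct[i] <- NA_integer_
    } else {
      opacity[i] <- states[[sc]]$opacity
      pas[i] <- observer_respond(observer, sc, opacity[i])
      aware[i] <- aware_from_pas(sc, pas[i])
      rep_i <- observer_report_orientation(observer, sc, pas[i],
                                           sched$orientation[i])
      correct[i] <- rep_i$correct
      states[[sc]] <- staircase_update(states[[sc]], cfgs[[sc]], aware[i])
    }
  }
  trials <- data.frame(
    trial_index = seq_len(n) - 1L,
    staircase = sched$staircase,
    opacity = opacity,
    orientation = sched$orientation,
    pas = pas,
    aware = aware,
    threshold_dummy = ifelse(sched$staircase == "detect", 1L,
                             ifelse(sched$staircase == "identify", 0L,
                                    NA_integer_)),
    correct = correct,
    stringsAsFactors = FALSE)
  list(trials = trials,
       detect_state = states$detect,
       identify_state = states$identify)
}

#' Luminance-equivalence recoding map
#'
#' On the display, distinct software opacity levels can produce identical
#' physical luminance changes. The recoding map partitions the opacity grid
#' into equivalence classes of levels with identical luminance; recoding
#' replaces each level by its class mean.
#'
#' @param classes A list of numeric vectors; each vector is one equivalence
#'   class of opacity levels. Classes must be disjoint.
#' @return An object of class \code{luminance_map}.
#' @export
luminance_map <- function(classes) {
  stopifnot(is.list(classes), length(classes) >= 1)
  all_levels <- unlist(classes)
  if (anyDuplicated(all_levels)) {
    stop("luminance classes must be disjoint", call. = FALSE)
  }
  classes <- lapply(unname(classes), unname)
  all_levels <- unname(all_levels)
  means <- vapply(classes, mean, numeric(1))
  for (i in seq_along(classes)) {
    rng <- range(classes[[i]])
    stopifnot(means[i] >= rng[1], means[i] <= rng[2])
  }
  structure(list(classes = classes, means = means,
                 levels = all_levels,
                 level_mean = rep(means, lengths(classes))),
            class = "luminance_map")
}

#' Recode opacity levels to luminance-class means
#'
#' Each input level is replaced by the mean of its luminance-equivalence
#' class. The operation is idempotent because class means are mapped to
#' themselves (every class mean lies within its class span and recoding a
#' recoded value finds the same class).
#'
#' @param levels Numeric vector of opacity levels.
#' @param lum_map A \code{\link{luminance_map}}.
#' @return Numeric vector of recoded levels.
#' @export
recode_opacity <- function(levels, lum_map) {
  idx <- match(levels, lum_map$levels)
  out <- lum_map$level_mean[idx]
  # a class mean is itself a valid input even when not on the original grid
  miss <- is.na(idx)
  if (any(miss)) {
    m2 <- match(levels[miss], lum_map$means)
    if (anyNA(m2)) {
      stop("opacity level(s) outside the luminance map: ",
           paste(utils::head(levels[miss][is.na(m2)], 5), collapse = ", "),
           call. = FALSE)
    }
    out[miss] <- lum_map$means[m2]
  }
  out
}
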