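#' ERP generator parameters
#'
#' Parameters of the synthetic single-trial ERP model. Each epoch spans
#' -100..800 ms around stimulus onset and contains (i) white Gaussian sensor
#' noise (optionally 1/f-shaped), (ii) a negative occipital component in the
#' visual-awareness-negativity (VAN) window, (iii) a positive centro-parietal
#' component in the late-positivity (LP) window, and (iv), on a small fraction
#' of trials, a large low-frequency drift emulating a movement/electrode
#' artifact. Component amplitudes are expressed as the window mean they
#' produce: on an aware trial at the detection threshold with zero opacity
#' deviation and zero subject deviation, the VAN-window mean over the VAN
#' electrodes equals \code{van_effect_detect} exactly.
#'
#' @param van_effect_detect,van_effect_identify Awareness effect (aware minus
#'   unaware) on the VAN window mean, in microvolts, at each threshold.
#' @param lp_effect_detect,lp_effect_identify Same for the LP window mean.
#' @param van_opacity_slope,lp_opacity_slope Window-mean change per opacity
#'   unit of deviation from the subject's threshold.
#' @param subject_sd Between-subject SD (microvolts) of each awareness effect.
#' @param noise_sd Per-sample noise SD in microvolts.
#' @param noise One of \code{"white"} or \code{"pink"} (1/f-shaped).
#' @param artifact_rate Probability that an epoch carries an injected
#'   large-range artifact.
#' @param artifact_amp Peak amplitude (microvolts) of the injected drift.
#' @param van_window,lp_window Two-element vectors, window bounds in ms.
#' @param van_electrodes,lp_electrodes Channel names of the two measurement
#'   sets; must be disjoint.
#' @param channels All channel names of a generated epoch.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class \code{erp_gen_params}.
#' @export
erp_gen_params <- function(van_effect_detect = -2.12,
                           van_effect_identify = -0.46,
                           lp_effect_detect = 1.83,
                           lp_effect_identify = 0.43,
                           van_opacity_slope = -3.61,
                           lp_opacity_slope = 3.19,
                           subject_sd = 0.8,
                           noise_sd = 25,
                           noise = c("white", "pink"),
                           artifact_rate = 0.04,
                           artifact_amp = 300,
                           van_window = c(180, 280),
                           lp_window = c(350, 550),
                           van_electrodes = c("O1", "O2", "PO3", "PO4",
                                              "PO7", "PO8"),
                           lp_electrodes = c("Pz", "P1", "P2", "CPz",
                                             "CP1", "CP2"),
                           channels = NULL,
                           sample_rate = 512) {
  noise <- match.arg(noise)
  if (is.null(channels)) {
    channels <- c(van_electrodes, lp_electrodes, "Oz", "Cz")
  }
  stopifnot(noise_sd > 0, sample_rate > 0,
            length(intersect(van_electrodes, lp_electrodes)) == 0,
            all(van_electrodes %in% channels),
            all(lp_electrodes %in% channels),
            van_window[1] < van_window[2], lp_window[1] < lp_window[2],
            van_window[1] >= -100, van_window[2] <= 800,
            lp_window[1] >= -100, lp_window[2] <= 800,
            artifact_rate >= 0, artifact_rate <= 1)
  structure(list(van_effect_detect = van_effect_detect,
                 van_effect_identify = van_effect_identify,
                 lp_effect_detect = lp_effect_detect,
                 lp_effect_identify = lp_effect_identify,
                 van_opacity_slope = van_opacity_slope,
                 lp_opacity_slope = lp_opacity_slope,
                 subject_sd = subject_sd, noise_sd = noise_sd, noise = noise,
                 artifact_rate = artifact_rate, artifact_amp = artifact_amp,
                 van_window = van_window, lp_window = lp_window,
                 van_electrodes = van_electrodes,
                 lp_electrodes = lp_electrodes,
                 channels = channels, sample_rate = sample_rate),
            class = "erp_gen_params")
}

#' Construct an epoch object
#'
#' An epoch is a channel-by-time matrix of amplitudes in microvolts with a
#' time axis in milliseconds relative to stimulus onset.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param channels Character vector of channel names (row names).
#' @param times_ms Numeric vector of sample times in ms.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class \code{erp_epoch}.
#' @export
erp_epoch <- function(data, channels, times_ms, sample_rate) {
  stopifnot(nrow(data) == length(channels), ncol(data) == length(times_ms))
  rownames(data) <- channels
  structure(list(data = data, channels = channels, times_ms = times_ms,
                 sample_rate = sample_rate),
            class = "erp_epoch")
}

#' @export
print.erp_epoch <- function(x, ...) {
  cat(sprintf("ERP epoch: %d channels x %d samples, %.1f..%.1f ms @ %g Hz\n",
              length(x$channels), length(x$times_ms),
              min(x$times_ms), max(x$times_ms), x$sample_rate))
  invisible(x)
}

# Time axis covering at least [-100, 800] ms at the given rate.
epoch_times <- function(sample_rate) {
  k <- seq(floor(-0.1 * sample_rate), ceiling(0.8 * sample_rate))
  k * 1000 / sample_rate
}

# Raised-cosine time course over [t0, t1], normalized so that its mean over
# the window samples of the given time axis is exactly 1. Zero elsewhere.
raised_cosine_bump <- function(times_ms, window) {
  inside <- times_ms >= window[1] & times_ms <= window[2]
  if (!any(inside)) stop("bump window contains no samples", call. = FALSE)
  shape <- numeric(length(times_ms))
  phase <- (times_ms[inside] - window[1]) / (window[2] - window[1])
  shape[inside] <- 1 - cos(2 * pi * phase)
  shape / mean(shape[inside])
}

# Per-channel noise matrix. Pink noise is white noise whose spectrum is
# shaped by 1/sqrt(f), rescaled to the requested per-sample SD.
epoch_noise <- function(n_ch, n_t, noise_sd, type) {
  m <- matrix(stats::rnorm(n_ch * n_t, sd = noise_sd), n_ch, n_t)
  if (type == "pink") {
    f <- seq_len(n_t) - 1
    f[1] <- 1  # keep DC finite; baseline correction removes it anyway
    scale <- 1 / sqrt(pmin(f, n_t - f + 1))
    sp <- t(apply(m, 1, function(x) Re(stats::fft(stats::fft(x) * scale,
                                                  inverse = TRUE)) / n_t))
    m <- sp * (noise_sd / stats::sd(as.vector(sp)))
  }
  m
}

#' Simulate one single-trial ERP epoch
#'
#' The epoch is the sum of sensor noise, a VAN bump restricted to the VAN
#' electrodes and window, and an LP bump restricted to the LP electrodes and
#' window. Bump amplitudes follow the linear trial model
#' \code{aware * effect(threshold) + opacity_dev * slope + subject_dev}.
#' With probability \code{artifact_rate} (or when \code{force_artifact} is
#' set) a half-sine drift of amplitude \code{artifact_amp} spanning the whole
#' epoch is added on all channels, and the returned epoch carries
#' \code{attr(, "is_artifact") = TRUE} as generator ground truth.
#'
#' @param params An \code{\link{erp_gen_params}} object.
#' @param aware 0/1 awareness on the trial.
#' @param threshold \code{"detect"} or \code{"identify"}.
#' @param opacity_dev Opacity deviation (opacity units) driving the slope
#'   term; the session generator passes opacity minus the subject's threshold.
#' @param subject_dev_van,subject_dev_lp Subject-level deviations of the two
#'   awareness effects (microvolts), applied only on aware trials.
#' @param force_artifact Logical; \code{NA} (default) draws artifact status at
#'   \code{artifact_rate}, otherwise forces the given status.
#' @return An \code{\link{erp_epoch}} with attribute \code{is_artifact}.
#' @export
simulate_epoch <- function(params, aware, threshold = c("detect", "identify"),
                           opacity_dev = 0, subject_dev_van = 0,
                           subject_dev_lp = 0, force_artifact = NA) {
  threshold <- match.arg(threshold)
  times <- epoch_times(params$sample_rate)
  n_t <- length(times)
  n_ch <- length(params$channels)
  dat <- epoch_noise(n_ch, n_t, params$noise_sd, params$noise)
  van_eff <- if (threshold == "detect") params$van_effect_detect else
    params$van_effect_identify
  lp_eff <- if (threshold == "detect") params$lp_effect_detect else
    params$lp_effect_identify
  van_amp <- aware * (van_eff + subject_dev_van) +
    opacity_dev * params$van_opacity_slope
  lp_amp <- aware * (lp_eff + subject_dev_lp) +
    opacity_dev * params$lp_opacity_slope
  if (van_amp != 0) {
    bump <- van_amp * raised_cosine_bump(times, params$van_window)
    rows <- match(params$van_electrodes, params$channels)
    dat[rows, ] <- dat[rows, ] + rep(bump, each = length(rows))
  }
  if (lp_amp != 0) {
    bump <- lp_amp * raised_cosine_bump(times, params$lp_window)
    rows <- match(params$lp_electrodes, params$channels)
    dat[rows, ] <- dat[rows, ] + rep(bump, each = length(rows))
  }
  is_artifact <- if (is.na(force_artifact)) {
    stats::runif(1) < params$artifact_rate
  } else {
    isTRUE(force_artifact)
  }
  if (is_artifact) {
    drift <- params$artifact_amp * sin(pi * seq(0, 1, length.out = n_t))
    dat <- dat + rep(drift, each = n_ch)
  }
  ep <- erp_epoch(dat, params$channels, times, params$sample_rate)
  attr(ep, "is_artifact") <- is_artifact
  ep
}
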