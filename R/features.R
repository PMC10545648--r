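#' Measurement window specification
#'
#' @param t_start,t_end Window bounds in ms relative to stimulus onset
#'   (inclusive on both ends at the sample grid).
#' @param electrodes Non-empty character vector of channel names.
#' @return An object of class \code{window_spec}.
#' @export
window_spec <- function(t_start, t_end, electrodes) {
  stopifnot(t_start < t_end, length(electrodes) >= 1)
  structure(list(t_start = t_start, t_end = t_end,
                 electrodes = electrodes),
            class = "window_spec")
}

#' Baseline-correct an epoch
#'
#' Subtracts, per channel, the mean amplitude over the pre-stimulus interval
#' [-100, 0) ms. The baseline mean of the result is zero by construction.
#'
#' @param epoch An \code{\link{erp_epoch}}.
#' @return The corrected epoch (attributes preserved).
#' @export
baseline_correct <- function(epoch) {
  bl <- epoch$times_ms >= -100 & epoch$times_ms < 0
  if (!any(bl)) stop("epoch has no samples in the [-100, 0) ms baseline",
                     call. = FALSE)
  means <- rowMeans(epoch$data[, bl, drop = FALSE])
  epoch$data <- epoch$data - means
  epoch
}

#' Window mean amplitude
#'
#' Arithmetic mean over all samples with time in [t_start, t_end] (both ends
#' inclusive) on the listed electrodes. This is the trial-level outcome
#' measure for both the VAN and the LP analyses.
#'
#' @param epoch A baseline-corrected \code{\link{erp_epoch}}.
#' @param window A \code{\link{window_spec}}.
#' @return The mean amplitude in microvolts.
#' @export
mean_amplitude <- function(epoch, window) {
  rows <- match(window$electrodes, epoch$channels)
  if (anyNA(rows)) {
    stop("electrode(s) not present in epoch: ",
         paste(window$electrodes[is.na(rows)], collapse = ", "),
         call. = FALSE)
  }
  cols <- epoch$times_ms >= window$t_start & epoch$times_ms <= window$t_end
  if (!any(cols)) stop("no samples fall inside the window", call. = FALSE)
  mean(epoch$data[rows, cols, drop = FALSE])
}

# Zero-phase FIR low-pass applied along time to all channels at once.
# A symmetric windowed-sinc (Hamming) filter applied with stats::filter
# (sides = 2) has exactly linear phase, so no forward-backward pass is
# needed. Edges are padded by reflection to avoid NA trimming.
fir_lowpass <- function(data, sample_rate, cutoff_hz, order = 64) {
  h <- signal::fir1(order, cutoff_hz / (sample_rate / 2), type = "low")
  h <- h / sum(h)  # exact unity DC gain
  n <- ncol(data)
  pad <- length(h)
  left <- data[, pmin((pad + 1):2, n), drop = FALSE]
  right <- data[, pmax((n - 1):(n - pad), 1), drop = FALSE]
  ext <- cbind(left, data, right)
  out <- t(stats::filter(t(ext), h, sides = 2))
  out[, pad + seq_len(n), drop = FALSE]
}

#' Peak-to-peak range of an epoch after a 30-Hz low-pass
#'
#' @param epoch An \code{\link{erp_epoch}}.
#' @param cutoff_hz Low-pass cutoff before the range is taken.
#' @return Maximum over channels of the within-channel amplitude range.
#' @export
epoch_range <- function(epoch, cutoff_hz = 30) {
  sm <- fir_lowpass(epoch$data, epoch$sample_rate, cutoff_hz)
  max(apply(sm, 1, function(x) diff(range(x))))
}

#' Flag artifact epochs by their amplitude range
#'
#' Deterministic replacement for blinded visual inspection: per subject, an
#' epoch is flagged when its maximum peak-to-peak range (after a 30-Hz
#' low-pass) exceeds \code{median(range) + k * MAD(range)}. Because a
#' degenerate session of identical epochs has zero MAD, the threshold never
#' falls below \code{median + floor_uv}.
#'
#' @param ranges Numeric vector of per-epoch ranges (see
#'   \code{\link{epoch_range}}), all from one subject.
#' @param k Multiplier on the MAD (default 5).
#' @param floor_uv Absolute floor (microvolts) on the distance above the
#'   median required for flagging.
#' @return Logical vector, \code{TRUE} for flagged epochs.
#' @export
flag_artifacts <- function(ranges, k = 5, floor_uv = 10) {
  med <- stats::median(ranges)
  threshold <- med + max(k * stats::mad(ranges), floor_uv)
  ranges > threshold
}

#' Downsample an epoch by an integer factor
#'
#' Applies a zero-phase FIR anti-alias low-pass at 80\% of the target Nyquist
#' frequency, then keeps every \code{factor}-th sample. Band-limited content
#' (such as ERP components) is preserved within the filter's passband ripple.
#'
#' @param epoch An \code{\link{erp_epoch}}.
#' @param factor Positive integer decimation factor.
#' @return The downsampled epoch.
#' @export
downsample_epoch <- function(epoch, factor) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor)) {
    stop("factor must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(epoch)
  new_rate <- epoch$sample_rate / factor
  sm <- fir_lowpass(epoch$data, epoch$sample_rate, 0.8 * new_rate / 2)
  keep <- seq(1, ncol(sm), by = factor)
  ia <- attr(epoch, "is_artifact")
  out <- erp_epoch(sm[, keep, drop = FALSE], epoch$channels,
                   epoch$times_ms[keep], new_rate)
  if (!is.null(ia)) attr(out, "is_artifact") <- ia
  out
}
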