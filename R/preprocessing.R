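#' Construct a multichannel recording
#'
#' @param signals Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional character vector of channel labels.
#' @param start_time Optional start timestamp (POSIXct), informational only.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(signals, fs, channel_names = NULL, start_time = NULL) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    rps_error("`signals` must be a numeric matrix (channels x samples)",
              "rps_usage_error")
  }
  if (any(!is.finite(signals))) {
    rps_error("`signals` contains non-finite samples", "rps_usage_error")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    rps_error("`fs` must be a positive scalar", "rps_usage_error")
  }
  if (ncol(signals) < fs) {
    rps_error("recording must contain at least one second of data",
              "rps_usage_error")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("EEG", seq_len(nrow(signals)))
  }
  if (length(channel_names) != nrow(signals)) {
    rps_error("`channel_names` length must match the channel count",
              "rps_usage_error")
  }
  rownames(signals) <- channel_names
  structure(list(signals = signals, fs = fs,
                 channel_names = channel_names, start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs, ncol(x$signals) / x$fs))
  invisible(x)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth low-pass applied forward-backward
#' ([signal::filtfilt()]) so event timing is preserved.  Sleep EEG is filtered
#' under 30 Hz by default to retain the frequencies that characterise sleep
#' stages while removing muscle-band energy.
#'
#' @param rec An `eeg_recording`.
#' @param cutoff_hz Cutoff frequency; must be below Nyquist.
#' @param order Filter order (default 4).
#' @return A filtered `eeg_recording` of identical shape.
#' @export
lowpass_filter <- function(rec, cutoff_hz = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cutoff_hz >= rec$fs / 2) {
    rps_error("`cutoff_hz` must be below the Nyquist frequency",
              "rps_usage_error")
  }
  bf <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "low")
  filt <- t(apply(rec$signals, 1, function(x) signal::filtfilt(bf, x)))
  new_recording(filt, rec$fs, rec$channel_names, rec$start_time)
}

#' Zero-phase high-pass filter (optional; off by default in the pipeline)
#'
#' @inheritParams lowpass_filter
#' @export
highpass_filter <- function(rec, cutoff_hz = 0.5, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cutoff_hz >= rec$fs / 2 || cutoff_hz <= 0) {
    rps_error("`cutoff_hz` must lie in (0, Nyquist)", "rps_usage_error")
  }
  bf <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "high")
  filt <- t(apply(rec$signals, 1, function(x) signal::filtfilt(bf, x)))
  new_recording(filt, rec$fs, rec$channel_names, rec$start_time)
}

#' Spatial covariance of one epoch
#'
#' Uncentered sample covariance \eqn{C = X X^\top / (m - 1)} (no per-epoch mean
#' subtraction by default; EEG is hardware high-passed so channel means are
#' near zero).  Optionally blended with a scaled identity:
#' \eqn{(1-\gamma) C + \gamma\,\mathrm{tr}(C)/n\, I}.
#'
#' @param x Numeric matrix, channels x samples.
#' @param shrinkage Shrinkage weight in `[0, 1)`.
#' @param center If `TRUE`, subtract each channel's mean first.
#' @return An SPD covariance matrix.
#' @export
epoch_covariance <- function(x, shrinkage = 0, center = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    rps_error("`x` must be a numeric matrix (channels x samples)",
              "rps_usage_error")
  }
  n <- nrow(x); m <- ncol(x)
  if (shrinkage < 0 || shrinkage >= 1) {
    rps_error("`shrinkage` must lie in [0, 1)", "rps_usage_error")
  }
  if (shrinkage == 0 && m <= n) {
    rps_error("epoch has fewer samples than channels + 1; the covariance is rank-deficient (use shrinkage)",
              "rps_invalid_matrix")
  }
  if (center) x <- x - rowMeans(x)
  C <- tcrossprod(x) / (m - 1)
  C <- (C + t(C)) / 2
  if (shrinkage > 0) {
    C <- (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / n) * diag(n)
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev)) {
    rps_error("epoch covariance is rank-deficient (duplicated or silent channel?); consider shrinkage",
              "rps_invalid_matrix")
  }
  unname(C)
}

#' Split a recording into non-overlapping epochs with covariances
#'
#' @param rec An `eeg_recording`.
#' @param epoch_length_s Epoch length in seconds (default 1).
#' @param shrinkage,center Passed to [epoch_covariance()].
#' @return An object of class `epoch_set`: list with `epochs`, `start_indices`
#'   (1-based sample offsets), `epoch_length_s`, `fs` and `covariances`.
#' @export
split_epochs <- function(rec, epoch_length_s = 1, shrinkage = 0, center = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (epoch_length_s <= 0) {
    rps_error("`epoch_length_s` must be positive", "rps_usage_error")
  }
  m <- round(epoch_length_s * rec$fs)
  n <- nrow(rec$signals)
  if (m < n + 1 && shrinkage == 0) {
    rps_error("epoch too short for a full-rank covariance (need epoch_length_s * fs >= channels + 1)",
              "rps_usage_error")
  }
  n_ep <- floor(ncol(rec$signals) / m)
  if (n_ep < 1) {
    rps_error("recording shorter than one epoch", "rps_usage_error")
  }
  starts <- (seq_len(n_ep) - 1L) * m + 1L
  epochs <- lapply(starts, function(s) rec$signals[, s:(s + m - 1), drop = FALSE])
  covs <- lapply(epochs, epoch_covariance, shrinkage = shrinkage, center = center)
  structure(list(epochs = epochs, start_indices = starts,
                 epoch_length_s = epoch_length_s, fs = rec$fs,
                 covariances = covs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s (%d channels)\n",
              length(x$epochs), x$epoch_length_s, nrow(x$epochs[[1]])))
  invisible(x)
}
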