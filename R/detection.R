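#' Sliding-window outlier scores against a fitted model
#'
#' Slides a window of `window_s` seconds with a step of
#' `round(step_fraction * fs)` samples over the (already filtered) recording.
#' Each window's spatial covariance is compared to every cluster centroid; the
#' distance to the nearest centroid is standardized by that cluster's
#' \eqn{(\mu_j, \sigma_j)} and mapped through the standard Gaussian CDF.  The
#' reported score is `p_outlier = pnorm(z)`: it increases with distance, so a
#' window at one geometric SD above the cluster mean scores about 0.84, and
#' 1.645 SDs score 0.95.
#'
#' @param rec A filtered `eeg_recording`.
#' @param model An `rp_model`.
#' @param window_s Window length in seconds.
#' @param step_fraction Step as a fraction of the sampling rate.
#' @param shrinkage,center Covariance options (should match the fit).
#' @return A tibble with `center_sample` (1-based), `p_outlier`, `z`,
#'   `nearest_cluster`.
#' @export
window_scores <- function(rec, model, window_s = 1, step_fraction = 0.1,
                          shrinkage = 0, center = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(model, "rp_model"))
  fs <- rec$fs
  n <- nrow(rec$signals)
  if (n != model$n_channels) {
    rps_error("recording channel count does not match the model",
              "rps_usage_error")
  }
  w <- round(window_s * fs)
  if (w <= n && shrinkage == 0) {
    rps_error("window too short: need window_s * fs > channel count",
              "rps_usage_error")
  }
  step <- max(1L, round(step_fraction * fs))
  T_ <- ncol(rec$signals)
  if (T_ < w) {
    rps_error("recording shorter than one window", "rps_usage_error")
  }
  starts <- seq.int(1L, T_ - w + 1L, by = step)
  covs <- lapply(starts, function(s) {
    epoch_covariance(rec$signals[, s:(s + w - 1), drop = FALSE],
                     shrinkage = shrinkage, center = center)
  })
  D <- with_spd_errors(cpp_cross_distances(covs, model$centroids))
  jstar <- max.col(-D, ties.method = "first")
  dstar <- D[cbind(seq_along(starts), jstar)]
  z <- vapply(seq_along(dstar), function(i) {
    standardize_distance(max(dstar[i], 1e-12), model$stats[[jstar[i]]])
  }, numeric(1))
  tibble::tibble(center_sample = starts + ((w - 1L) %/% 2L),
                 p_outlier = pnorm(z), z = z, nearest_cluster = jstar)
}

#' Build a per-sample score trace from window anchors
#'
#' Linear interpolation between consecutive window-center anchors, with
#' additional zero anchors at the first and last sample of the recording (the
#' scoring starts and ends at 0).  Values are clipped to `[0, 1]`.
#'
#' @param scores Tibble/data frame with `center_sample` and `p_outlier`
#'   (strictly increasing centers), as returned by [window_scores()].
#' @param rec_length Recording length in samples.
#' @param fs Sampling rate in Hz.
#' @param window_s,step_samples Metadata stored on the trace.
#' @return An object of class `rp_trace`: list with `p_outlier` (length
#'   `rec_length`), `fs`, `window_s`, `step_samples`.
#' @export
build_trace <- function(scores, rec_length, fs, window_s = 1,
                        step_samples = max(1L, round(0.1 * fs))) {
  if (NROW(scores) == 0) {
    rps_error("no window scores to interpolate", "rps_usage_error")
  }
  cs <- scores$center_sample
  pv <- scores$p_outlier
  if (any(diff(cs) <= 0)) {
    rps_error("`center_sample` must be strictly increasing", "rps_usage_error")
  }
  x <- cs; y <- pv
  if (cs[1] > 1) { x <- c(1, x); y <- c(0, y) } else y[1] <- 0
  if (cs[length(cs)] < rec_length) {
    x <- c(x, rec_length); y <- c(y, 0)
  } else y[length(y)] <- 0
  p <- approx(x, y, xout = seq_len(rec_length), rule = 2)$y
  p <- pmin(pmax(p, 0), 1)
  structure(list(p_outlier = p, fs = fs, window_s = window_s,
                 step_samples = as.integer(step_samples)),
            class = "rp_trace")
}

#' Smooth a score trace with a centered moving average
#'
#' Edge-truncated centered moving average of `round(window_s * fs)` samples;
#' preserves the `[0, 1]` range and never increases the global maximum.
#'
#' @param trace An `rp_trace`.
#' @param window_s Smoothing window in seconds.
#' @return A smoothed `rp_trace`.
#' @export
smooth_trace <- function(trace, window_s = 0.5) {
  stopifnot(inherits(trace, "rp_trace"))
  if (window_s <= 0) rps_error("`window_s` must be positive", "rps_usage_error")
  w <- round(window_s * trace$fs)
  if (w <= 1) return(trace)
  x <- trace$p_outlier
  T_ <- length(x)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  cs <- c(0, cumsum(x))
  i <- seq_len(T_)
  lo <- pmax(1L, i - hl)
  hi <- pmin(T_, i + hr)
  trace$p_outlier <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  trace
}

# Indices of strict local minima over a 3-sample neighbourhood; a plateau lower
# than both neighbours counts as one minimum at its center.
local_minima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(k - 1)
  is_min <- r$values[j] < r$values[j - 1] & r$values[j] < r$values[j + 1]
  mids <- (starts[j] + ends[j]) %/% 2L
  mids[is_min]
}

#' Segment a trace at local minima and threshold into artifact segments
#'
#' Segment boundaries are the strict local minima of the (smoothed) trace plus
#' the recording ends.  A segment is emitted as an artifact iff its samples
#' above `threshold` span at least `min_duration_s`; the emitted interval is
#' the segment's supra-threshold run.  Emitted runs separated by less than one
#' window step are merged.
#'
#' @param trace An `rp_trace` (typically smoothed).
#' @param threshold Outlier-probability threshold in (0, 1).
#' @param min_duration_s Minimum artifact duration in seconds (default 0.4).
#' @return Tibble of disjoint, sorted segments: `start_s`, `end_s` (half-open
#'   `[start, end)`), `peak_score`, `source = "detector"`.
#' @export
segment_and_threshold <- function(trace, threshold = 0.95, min_duration_s = 0.4) {
  stopifnot(inherits(trace, "rp_trace"))
  if (threshold <= 0 || threshold >= 1) {
    rps_error("`threshold` must lie in (0, 1)", "rps_usage_error")
  }
  x <- trace$p_outlier
  fs <- trace$fs
  T_ <- length(x)
  bounds <- c(1L, local_minima(x), T_ + 1L)
  bounds <- sort(unique(bounds))
  min_samples <- min_duration_s * fs
  runs <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    seg <- bounds[b]:(bounds[b + 1L] - 1L)
    above <- seg[x[seg] > threshold]
    if (length(above) >= min_samples) {
      first <- min(above); last <- max(above)
      runs[[length(runs) + 1L]] <-
        c(first, last, max(x[first:last]))
    }
  }
  if (length(runs) == 0) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          peak_score = numeric(0), source = character(0)))
  }
  m <- do.call(rbind, runs)
  # merge emitted runs separated by less than one step
  merged <- list(m[1, ])
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      prev <- merged[[length(merged)]]
      if (m[i, 1] - prev[2] < trace$step_samples) {
        merged[[length(merged)]] <- c(prev[1], m[i, 2], max(prev[3], m[i, 3]))
      } else {
        merged[[length(merged) + 1L]] <- m[i, ]
      }
    }
  }
  m <- do.call(rbind, merged)
  tibble::tibble(start_s = (m[, 1] - 1) / fs, end_s = m[, 2] / fs,
                 peak_score = m[, 3], source = "detector")
}

#' Detect artifacts in a recording with a fitted model
#'
#' Composition of the scoring pipeline: low-pass filtering, sliding-window
#' scoring, per-sample interpolation, moving-average smoothing and
#' local-minima segmentation with the minimum-duration rule.  Deterministic
#' given the inputs and configuration.
#'
#' @param rec An `eeg_recording` (unfiltered; the configured low-pass is
#'   applied here).
#' @param model An `rp_model` with matching channel count.
#' @param config An [rp_config()]; defaults to the model's own configuration.
#' @return An object of class `rp_detection`: list with `trace` (smoothed
#'   `rp_trace`), `scores` (window anchors) and `segments` (tibble).
#' @export
rp_detect <- function(rec, model, config = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(model, "rp_model"))
  config <- validate_config(config %||% model$config %||% rp_config())
  if (nrow(rec$signals) != model$n_channels) {
    rps_error("recording channel count does not match the model",
              "rps_usage_error")
  }
  filtered <- lowpass_filter(rec, config$lowpass_hz)
  if (!is.null(config$highpass_hz)) {
    filtered <- highpass_filter(filtered, config$highpass_hz)
  }
  scores <- window_scores(filtered, model, window_s = config$window_s,
                          step_fraction = config$step_fraction,
                          shrinkage = config$shrinkage, center = config$center)
  step <- max(1L, round(config$step_fraction * rec$fs))
  trace <- build_trace(scores, ncol(rec$signals), rec$fs,
                       window_s = config$window_s, step_samples = step)
  trace <- smooth_trace(trace, config$smooth_window_s)
  segments <- segment_and_threshold(trace, config$threshold,
                                    config$min_duration_s)
  structure(list(trace = trace, scores = scores, segments = segments,
                 config = config),
            class = "rp_detection")
}

#' @export
print.rp_detection <- function(x, ...) {
  dur <- sum(x$segments$end_s - x$segments$start_s)
  total <- length(x$trace$p_outlier) / x$trace$fs
  cat(sprintf("<rp_detection> %d artifact segment(s), %.1f s flagged (%.1f%% of %.1f s)\n",
              nrow(x$segments), dur, 100 * dur / total, total))
  invisible(x)
}
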