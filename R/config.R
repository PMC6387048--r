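#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with its default.
#' Durations are in seconds, frequencies in Hz.
#'
#' @param epoch_length_s Training epoch length (default 1 s).
#' @param window_s Sliding scoring window length (default 1 s).
#' @param step_fraction Window step as a fraction of the sampling rate
#'   (default 0.1, i.e. step = round(0.1 * fs) samples).
#' @param lowpass_hz Low-pass cutoff (default 30 Hz).
#' @param highpass_hz Optional high-pass cutoff; `NULL` (default) disables it.
#' @param center Subtract per-epoch channel means before the covariance
#'   (default `FALSE`; the sample covariance is uncentered).
#' @param k_max Maximum number of clusters tried (default 10).
#' @param alpha Combined-normality acceptance level (default 0.05).
#' @param threshold Outlier-probability threshold for artifact segments
#'   (default 0.95, about 1.645 geometric SDs).
#' @param min_duration_s Minimum supra-threshold duration of an artifact
#'   (default 0.4 s).
#' @param smooth_window_s Moving-average smoothing window (default 0.5 s).
#' @param shrinkage Covariance shrinkage toward scaled identity (default 0).
#' @param seed Integer RNG seed for k-means initialisation.
#' @param min_cluster_size Minimum cluster size for the K2 normality test.
#' @param fuzzy_min_fraction Fuzzy-border leniency: minimum residual duration
#'   as a fraction of the adjacent expert artifact (default 0.10).
#' @param fuzzy_max_lenient_s Fuzzy-border leniency cap (default 1.5 s).
#' @param fuzzy_rule `"literal"` (default), `"cap"` or `"strict"`; see
#'   [fuzzy_confusion()].
#' @param prereject_stat Mean type for the pre-rejection threshold.
#' @param tol,max_iter Geometric-mean convergence controls.
#' @return A named list of class `rp_config`.
#' @export
rp_config <- function(epoch_length_s = 1.0, window_s = 1.0, step_fraction = 0.1,
                      lowpass_hz = 30, highpass_hz = NULL, center = FALSE,
                      k_max = 10L, alpha = 0.05, threshold = 0.95,
                      min_duration_s = 0.4, smooth_window_s = 0.5,
                      shrinkage = 0.0, seed = 1L, min_cluster_size = 20L,
                      fuzzy_min_fraction = 0.10, fuzzy_max_lenient_s = 1.5,
                      fuzzy_rule = c("literal", "cap", "strict"),
                      prereject_stat = c("arithmetic", "geometric"),
                      tol = 1e-7, max_iter = 100L) {
  cfg <- list(epoch_length_s = epoch_length_s, window_s = window_s,
              step_fraction = step_fraction, lowpass_hz = lowpass_hz,
              highpass_hz = highpass_hz, center = isTRUE(center),
              k_max = as.integer(k_max), alpha = alpha, threshold = threshold,
              min_duration_s = min_duration_s,
              smooth_window_s = smooth_window_s, shrinkage = shrinkage,
              seed = as.integer(seed),
              min_cluster_size = as.integer(min_cluster_size),
              fuzzy_min_fraction = fuzzy_min_fraction,
              fuzzy_max_lenient_s = fuzzy_max_lenient_s,
              fuzzy_rule = match.arg(fuzzy_rule),
              prereject_stat = match.arg(prereject_stat),
              tol = tol, max_iter = as.integer(max_iter))
  class(cfg) <- "rp_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!inherits(cfg, "rp_config")) {
    rps_error("`config` must be created with rp_config()", "rps_usage_error")
  }
  durs <- c(cfg$epoch_length_s, cfg$window_s, cfg$min_duration_s,
            cfg$smooth_window_s, cfg$fuzzy_max_lenient_s)
  if (any(durs <= 0)) {
    rps_error("all durations must be positive", "rps_usage_error")
  }
  if (cfg$threshold <= 0 || cfg$threshold >= 1) {
    rps_error("`threshold` must lie in (0, 1)", "rps_usage_error")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    rps_error("`alpha` must lie in (0, 1)", "rps_usage_error")
  }
  if (cfg$step_fraction <= 0) {
    rps_error("`step_fraction` must be positive", "rps_usage_error")
  }
  if (cfg$shrinkage < 0 || cfg$shrinkage >= 1) {
    rps_error("`shrinkage` must lie in [0, 1)", "rps_usage_error")
  }
  if (cfg$fuzzy_min_fraction < 0 || cfg$fuzzy_min_fraction > 1) {
    rps_error("`fuzzy_min_fraction` must lie in [0, 1]", "rps_usage_error")
  }
  cfg
}

#' @export
print.rp_config <- function(x, ...) {
  cat("<rp_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}
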