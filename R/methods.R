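#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-cluster summary of a fitted model
#'
#' @param x An `rp_model`.
#' @param ... Unused.
#' @return Tibble with one row per cluster: `cluster`, `size`, `mu`, `sigma`,
#'   `p_normality`.
#' @export
tidy.rp_model <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    size = vapply(x$stats, function(s) as.integer(s$count), integer(1)),
    mu = vapply(x$stats, function(s) s$mu, numeric(1)),
    sigma = vapply(x$stats, function(s) s$sigma, numeric(1)),
    p_normality = if (is.null(x$cluster_p)) rep(NA_real_, x$k) else x$cluster_p)
}

#' One-row summary of a fitted model
#'
#' @param x An `rp_model`.
#' @param ... Unused.
#' @export
glance.rp_model <- function(x, ...) {
  tibble::tibble(k = x$k, combined_p = x$combined_p,
                 n_epochs = if (is.null(x$labels)) NA_integer_ else length(x$labels),
                 n_rejected = length(x$rejected_epochs),
                 inertia = x$inertia %||% NA_real_)
}

#' Detected segments of a detection result
#'
#' @param x An `rp_detection`.
#' @param ... Unused.
#' @export
tidy.rp_detection <- function(x, ...) x$segments

#' Plot a score trace
#'
#' @param object An `rp_trace`.
#' @param threshold Optional threshold to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rp_trace <- function(object, threshold = NULL, ...) {
  df <- data.frame(time_s = (seq_along(object$p_outlier) - 1) / object$fs,
                   p_outlier = object$p_outlier)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$p_outlier)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "outlier probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot a detection result (trace plus flagged segments)
#'
#' @param object An `rp_detection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rp_detection <- function(object, ...) {
  p <- autoplot.rp_trace(object$trace, threshold = object$config$threshold)
  if (nrow(object$segments)) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(object$segments),
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = 0, ymax = 1),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.2)
  }
  p
}

#' @importFrom ggplot2 .data
NULL
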