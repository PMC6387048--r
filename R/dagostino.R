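#' D'Agostino's K2 omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) z statistics into \eqn{K^2 = Z_1^2 + Z_2^2}, which
#' is approximately chi-squared with 2 degrees of freedom under normality.
#' Moment transformations follow the standard formulation, so results agree
#' with other implementations of the omnibus test.
#'
#' @param x Numeric vector, length >= 9 (the kurtosis approximation degrades
#'   badly below ~20 samples; callers gate on that).
#' @return List with `statistic` (K2), `p.value`, `z_skewness`, `z_kurtosis`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 9) {
    rps_error("K2 test requires at least 9 observations", "rps_usage_error")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) {
    rps_error("K2 test requires non-constant data", "rps_degenerate_error")
  }
  b1 <- mean((x - m)^3) / m2^1.5   # sample skewness g1
  b2 <- mean((x - m)^4) / m2^2     # sample kurtosis g2 (non-excess)

  # skewness z (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  y <- ifelse(y == 0, 1e-30, y)
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term <- sign(denom) * ((1 - 2 / A) / abs(denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * A)) - term) / sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p.value = pchisq(k2, df = 2, lower.tail = FALSE),
       log_p = pchisq(k2, df = 2, lower.tail = FALSE, log.p = TRUE),
       z_skewness = z1, z_kurtosis = z2)
}

#' Stouffer's Z-score combination of p-values
#'
#' One-sided combination: \eqn{Z = \sum_j \Phi^{-1}(1 - p_j) / \sqrt{k}},
#' combined p-value \eqn{1 - \Phi(Z)}.  P-values are clamped away from 0 and 1
#' to keep the normal quantiles finite.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Combined p-value.
#' @export
stouffer_combine <- function(p) {
  if (length(p) == 0 || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    rps_error("`p` must be p-values in [0, 1]", "rps_usage_error")
  }
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  z <- sum(qnorm(1 - p)) / sqrt(length(p))
  1 - pnorm(z)
}
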