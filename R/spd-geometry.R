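#' Affine-invariant Riemannian distance between SPD matrices
#'
#' Computes the geodesic distance between two symmetric positive-definite
#' (SPD) matrices under the affine-invariant (Fisher) metric,
#' \deqn{\delta(C_i, C_j) = \sqrt{\sum_i \log^2 \lambda_i},}
#' where \eqn{\lambda_i} are the generalized eigenvalues of the pair.  The
#' distance is symmetric, zero iff the matrices are equal, and invariant under
#' congruence transformations \eqn{A^\top C A} for any invertible \eqn{A}.
#'
#' @param a,b SPD matrices of identical dimension.
#' @return A non-negative scalar distance.
#' @examples
#' riemann_distance(diag(2), diag(c(exp(2), exp(2))))  # 2 * sqrt(2)
#' @export
riemann_distance <- function(a, b) {
  a <- check_square_symmetric(a, "a")
  b <- check_square_symmetric(b, "b")
  if (!identical(dim(a), dim(b))) {
    rps_error("`a` and `b` must have the same dimension", "rps_usage_error")
  }
  with_spd_errors(cpp_spd_distance(a, b))
}

#' Pairwise affine-invariant distances
#'
#' @param covs List of SPD matrices of identical dimension.
#' @return Symmetric matrix of pairwise distances with zero diagonal.
#' @export
pairwise_distances <- function(covs) {
  covs <- check_cov_list(covs)
  with_spd_errors(cpp_pairwise_distances(covs))
}

check_cov_list <- function(covs, arg = "covs") {
  if (!is.list(covs) || length(covs) == 0) {
    rps_error(sprintf("`%s` must be a non-empty list of SPD matrices", arg),
              "rps_usage_error")
  }
  covs <- lapply(seq_along(covs), function(i) {
    check_square_symmetric(covs[[i]], sprintf("%s[[%d]]", arg, i))
  })
  dims <- vapply(covs, nrow, integer(1))
  if (length(unique(dims)) != 1) {
    rps_error(sprintf("all matrices in `%s` must share one dimension", arg),
              "rps_usage_error")
  }
  covs
}

#' Geometric (Fréchet) mean of SPD matrices
#'
#' Fixed-point iteration for the geometric mean under the affine-invariant
#' metric.  Initialized at the arithmetic mean, the iterate is updated by
#' \deqn{M \leftarrow M^{1/2} \exp\!\Big[\tfrac1k \sum_k
#'   \log(M^{-1/2} C_k M^{-1/2})\Big] M^{1/2}}
#' until the Frobenius norm of the bracketed mean log map falls below `tol`.
#'
#' @param covs Non-empty list of SPD matrices of identical dimension.
#' @param tol Convergence tolerance on the Frobenius norm of the mean log map.
#' @param max_iter Maximum number of update steps.
#' @return The mean matrix, with attributes `iterations` and `final_residual`.
#' @export
geometric_mean <- function(covs, tol = 1e-7, max_iter = 100L) {
  covs <- check_cov_list(covs)
  res <- with_spd_errors(cpp_geometric_mean(covs, tol, as.integer(max_iter)))
  if (!res$converged) {
    stop(errorCondition(
      sprintf("geometric mean did not converge in %d iterations (residual %.3e)",
              max_iter, res$final_residual),
      class = c("rps_convergence_error", "rps_error"),
      residual = res$final_residual))
  }
  out <- res$mean
  attr(out, "iterations") <- res$iterations
  attr(out, "final_residual") <- res$final_residual
  out
}

#' Geometric mean and geometric standard deviation of a distance set
#'
#' For strictly positive distances \eqn{\delta_k}, computes
#' \eqn{\mu = \exp(\mathrm{mean}(\ln\delta_k))} and the geometric standard
#' deviation \eqn{\sigma = \exp\sqrt{\mathrm{mean}(\ln^2(\delta_k/\mu))}}.
#' The square root makes \eqn{\mu\sigma} mark one geometric SD, so that the
#' standardized distances [standardize_distance()] of the defining set have
#' arithmetic mean 0 and mean square 1.
#'
#' @param distances Numeric vector of strictly positive distances, length >= 2.
#' @return An object of class `distance_stats`: list with `mu`, `sigma`, `count`.
#' @export
distance_stats <- function(distances) {
  if (!is.numeric(distances) || length(distances) < 2) {
    rps_error("`distances` must be a numeric vector of length >= 2",
              "rps_usage_error")
  }
  if (any(!is.finite(distances)) || any(distances <= 0)) {
    rps_error(paste0("all distances must be strictly positive; a zero distance ",
                     "means a training epoch identical to the centroid ",
                     "(jitter or drop it)"),
              "rps_domain_error")
  }
  l <- log(distances)
  mu <- exp(mean(l))
  sigma <- exp(sqrt(mean((l - mean(l))^2)))
  structure(list(mu = mu, sigma = sigma, count = length(distances)),
            class = "distance_stats")
}

#' Standardized Riemannian distance
#'
#' Maps a distance onto the log scale of its cluster:
#' \eqn{\delta' = \ln(\delta/\mu) / \ln\sigma}.
#'
#' @param delta Positive distance (vectorized).
#' @param stats A [distance_stats()] object with `sigma > 1`.
#' @return Standardized distance(s).
#' @export
standardize_distance <- function(delta, stats) {
  if (!inherits(stats, "distance_stats")) {
    rps_error("`stats` must be a `distance_stats` object", "rps_usage_error")
  }
  if (any(!is.finite(delta)) || any(delta <= 0)) {
    rps_error("`delta` must be strictly positive", "rps_domain_error")
  }
  if (stats$sigma <= 1) {
    rps_error("degenerate dispersion: sigma must exceed 1 to standardize",
              "rps_degenerate_error")
  }
  log(delta / stats$mu) / log(stats$sigma)
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("Distance stats: mu = %.4g, sigma = %.4g (k = %d)\n",
              x$mu, x$sigma, x$count))
  invisible(x)
}
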