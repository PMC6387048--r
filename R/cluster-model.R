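#' Pre-reject gross outlier epochs by mean pairwise distance
#'
#' For each epoch covariance, computes \eqn{d_i}, the mean affine-invariant
#' distance from epoch \eqn{i} to all other epochs; epochs with \eqn{d_i}
#' strictly greater than the mean of all \eqn{d_i} are removed before
#' clustering.  When all epochs are identical the threshold is 0 and nothing is
#' strictly greater, so everything is kept.
#'
#' @param covs List of SPD matrices (>= 2).
#' @param stat Threshold statistic over the `d` values: `"arithmetic"`
#'   (default) or `"geometric"` mean.
#' @return List with `kept` and `rejected` index vectors (a partition of the
#'   input), the per-epoch `d` values and the `threshold` used.
#' @export
prereject_outliers <- function(covs, stat = c("arithmetic", "geometric")) {
  stat <- match.arg(stat)
  covs <- check_cov_list(covs)
  if (length(covs) < 2) {
    rps_error("need at least 2 covariance matrices", "rps_usage_error")
  }
  D <- with_spd_errors(cpp_pairwise_distances(covs))
  n <- length(covs)
  d <- rowSums(D) / (n - 1)
  threshold <- if (stat == "arithmetic") {
    mean(d)
  } else {
    if (any(d <= 0)) 0 else exp(mean(log(d)))
  }
  rejected <- which(d > threshold)
  kept <- setdiff(seq_len(n), rejected)
  list(kept = kept, rejected = rejected, d = d, threshold = threshold)
}

# Seeded k-means++-style initialisation with squared-distance weights.
seed_centroids <- function(covs, k) {
  n <- length(covs)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    dmin <- with_spd_errors(cpp_cross_distances(covs, covs[idx[1]]))[, 1]
    for (j in 2:k) {
      w <- dmin^2
      if (sum(w) <= 0) {
        # all remaining points coincide with a centroid; pick any unused one
        idx[j] <- setdiff(seq_len(n), idx[seq_len(j - 1)])[1]
      } else {
        idx[j] <- sample.int(n, 1, prob = w / sum(w))
      }
      dj <- with_spd_errors(cpp_cross_distances(covs, covs[idx[j]]))[, 1]
      dmin <- pmin(dmin, dj)
    }
  }
  idx
}

#' Riemannian k-means
#'
#' Alternates nearest-centroid assignment under the affine-invariant distance
#' (ties broken toward the lowest cluster index) with centroid updates by the
#' geometric mean of each cluster's members, until the labels stop changing or
#' `max_iter` is reached.  Initialisation is distance-weighted farthest-point
#' seeding driven by `seed`, so runs are fully reproducible.  An empty cluster
#' is re-seeded with the point currently farthest from its own centroid.
#'
#' @param covs List of SPD matrices.
#' @param k Number of clusters, `1 <= k <= length(covs)`.
#' @param seed Integer RNG seed.
#' @param max_iter Maximum assignment/update rounds.
#' @param tol,mean_max_iter Geometric-mean convergence controls.
#' @return List with `labels`, `centroids`, `inertia`
#'   (\eqn{\sum_i \delta^2(C_i, O_{l(i)})}), `inertia_trace` (one value per
#'   assignment step) and `iterations`.
#' @export
riemann_kmeans <- function(covs, k, seed = 1L, max_iter = 100L,
                           tol = 1e-7, mean_max_iter = 100L) {
  covs <- check_cov_list(covs)
  n <- length(covs)
  if (k < 1 || k > n) {
    rps_error("`k` must lie between 1 and the number of covariances",
              "rps_usage_error")
  }
  withr::with_seed(seed, {
    centroids <- covs[seed_centroids(covs, k)]
    labels <- rep(0L, n)
    inertia_trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      D <- with_spd_errors(cpp_cross_distances(covs, centroids))
      new_labels <- max.col(-D, ties.method = "first")
      # re-seed empty clusters with the point farthest from its own centroid
      for (j in which(tabulate(new_labels, k) == 0)) {
        far <- which.max(D[cbind(seq_len(n), new_labels)])
        new_labels[far] <- j
        centroids[[j]] <- covs[[far]]
        D[far, ] <- with_spd_errors(cpp_cross_distances(covs[far], centroids))[1, ]
      }
      inertia_trace <- c(inertia_trace,
                         sum(D[cbind(seq_len(n), new_labels)]^2))
      if (identical(new_labels, labels)) break
      labels <- new_labels
      centroids <- lapply(seq_len(k), function(j) {
        m <- geometric_mean(covs[labels == j], tol = tol,
                            max_iter = mean_max_iter)
        attr(m, "iterations") <- NULL
        attr(m, "final_residual") <- NULL
        m
      })
    }
    D <- with_spd_errors(cpp_cross_distances(covs, centroids))
    labels <- max.col(-D, ties.method = "first")
    list(labels = labels, centroids = lapply(centroids, unclass),
         inertia = sum(D[cbind(seq_len(n), labels)]^2),
         inertia_trace = inertia_trace, iterations = iter,
         member_distances = lapply(seq_len(k),
                                   function(j) D[labels == j, j]))
  })
}

# Combined normality over clusters: standardize each cluster's member
# distances, test each with K2, combine with Stouffer's Z.  Clusters below
# `min_size` members or with degenerate dispersion invalidate the
# configuration (p = 0) rather than raising.  The combination is carried in
# log-p precision so that configurations whose p-values would all underflow to
# zero still compare correctly (the tie-break toward smaller k is meant for
# genuine ties, not floating-point ones).
combined_normality <- function(dists_by_cluster, min_size = 20) {
  log_p <- vapply(dists_by_cluster, function(d) {
    if (length(d) < min_size) return(-Inf)
    d <- pmax(d, 1e-12)  # floor exact-zero distances to keep logs finite
    st <- distance_stats(d)
    if (st$sigma <= 1) return(-Inf)
    z <- standardize_distance(d, st)
    dagostino_k2(z)$log_p
  }, numeric(1))
  z <- qnorm(log_p, lower.tail = FALSE, log.p = TRUE)
  Z <- sum(z) / sqrt(length(z))
  list(cluster_p = exp(log_p), combined_p = pnorm(Z, lower.tail = FALSE),
       combined_z = Z)
}

#' Combined normality p-value of a fitted cluster model
#'
#' Standardizes each cluster's member distances to its centroid, applies
#' D'Agostino's K2 omnibus test per cluster and combines the per-cluster
#' p-values with Stouffer's Z-score method.  Undersized clusters score the
#' whole configuration as invalid (combined p = 0).
#'
#' @param model An `rp_model` (or any list carrying `member_distances`).
#' @param min_size Minimum cluster size for a reliable K2 test (default 20).
#' @return Combined p-value in `[0, 1]`.
#' @export
cluster_normality_p <- function(model, min_size = 20) {
  if (is.null(model$member_distances)) {
    rps_error("`model` must carry per-cluster member distances",
              "rps_usage_error")
  }
  combined_normality(model$member_distances, min_size)$combined_p
}

#' Select the number of clusters by the combined-normality stopping rule
#'
#' Runs Riemannian k-means for k = 1, 2, ..., `k_max` and returns the first
#' model whose combined normality p-value exceeds `alpha`; if none does, the
#' model with the greatest combined p-value is returned, ties broken toward
#' the smaller k.  The rationale: when within-cluster standardized distances
#' are Gaussian, the cluster is a good representative of a region of the
#' manifold and further splitting is unnecessary.
#'
#' @param covs List of SPD matrices (already pre-rejected).
#' @param k_max Maximum cluster count to try (default 10).
#' @param alpha Normality acceptance level (default 0.05).
#' @param seed Integer RNG seed for k-means initialisation.
#' @param min_cluster_size Minimum cluster size for the K2 test.
#' @param tol,max_iter Geometric-mean convergence controls.
#' @return An object of class `rp_model`.
#' @export
select_cluster_count <- function(covs, k_max = 10L, alpha = 0.05, seed = 1L,
                                 min_cluster_size = 20L,
                                 tol = 1e-7, max_iter = 100L) {
  covs <- check_cov_list(covs)
  if (length(covs) < min_cluster_size) {
    rps_error("fewer retained epochs than the minimum cluster size",
              "rps_usage_error")
  }
  if (k_max < 1) rps_error("`k_max` must be >= 1", "rps_usage_error")
  best <- NULL
  for (k in seq_len(min(k_max, length(covs)))) {
    km <- riemann_kmeans(covs, k, seed = seed, tol = tol,
                         mean_max_iter = max_iter)
    norm <- combined_normality(km$member_distances, min_cluster_size)
    model <- new_rp_model(km, norm, covs)
    # greatest combined p == smallest Stouffer Z, compared on the Z scale so
    # underflowing p-values still rank; ties break toward smaller k
    if (is.null(best) || model$combined_z < best$combined_z) best <- model
    if (model$combined_p > alpha) return(model)
  }
  best
}

new_rp_model <- function(km, norm, covs) {
  k <- length(km$centroids)
  stats <- lapply(seq_len(k), function(j) {
    d <- pmax(km$member_distances[[j]], 1e-12)
    if (length(d) >= 2) distance_stats(d) else
      structure(list(mu = if (length(d)) d else NA_real_,
                     sigma = 1, count = length(d)),
                class = "distance_stats")
  })
  structure(list(
    centroids = km$centroids,
    stats = stats,
    labels = km$labels,
    k = k,
    combined_p = norm$combined_p,
    combined_z = norm$combined_z,
    cluster_p = norm$cluster_p,
    member_distances = km$member_distances,
    inertia = km$inertia,
    n_channels = nrow(km$centroids[[1]]),
    rejected_epochs = integer(0),
    config = NULL,
    channel_names = NULL,
    fs = NULL,
    seed = NULL
  ), class = "rp_model")
}

#' Fit a Riemannian-potatoes model to a recording
#'
#' Full cluster-construction pipeline: zero-phase low-pass filtering,
#' non-overlapping epoching, per-epoch spatial covariances, pre-rejection of
#' gross outlier epochs by mean pairwise distance, then cluster-count selection
#' by the combined-normality rule.
#'
#' @param rec An `eeg_recording`.
#' @param config A [rp_config()] list.
#' @return An `rp_model` carrying centroids, per-cluster distance statistics,
#'   training labels, rejected-epoch indices and the configuration echo.
#' @export
rp_fit <- function(rec, config = rp_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  config <- validate_config(config)
  filtered <- lowpass_filter(rec, config$lowpass_hz)
  if (!is.null(config$highpass_hz)) {
    filtered <- highpass_filter(filtered, config$highpass_hz)
  }
  eps <- split_epochs(filtered, config$epoch_length_s,
                      shrinkage = config$shrinkage, center = config$center)
  pre <- prereject_outliers(eps$covariances, stat = config$prereject_stat)
  model <- select_cluster_count(eps$covariances[pre$kept],
                                k_max = config$k_max, alpha = config$alpha,
                                seed = config$seed,
                                min_cluster_size = config$min_cluster_size,
                                tol = config$tol, max_iter = config$max_iter)
  model$rejected_epochs <- pre$rejected
  model$config <- config
  model$channel_names <- rec$channel_names
  model$fs <- rec$fs
  model$seed <- config$seed
  model
}

#' @export
print.rp_model <- function(x, ...) {
  cat(sprintf("<rp_model> %d cluster(s) on %d channels; combined normality p = %.3g\n",
              x$k, x$n_channels, x$combined_p))
  for (j in seq_len(x$k)) {
    cat(sprintf("  cluster %d: %d epochs, mu = %.3g, sigma = %.3g\n",
                j, x$stats[[j]]$count, x$stats[[j]]$mu, x$stats[[j]]$sigma))
  }
  if (length(x$rejected_epochs)) {
    cat(sprintf("  pre-rejected epochs: %d\n", length(x$rejected_epochs)))
  }
  invisible(x)
}
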