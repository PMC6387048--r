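# Independent base-R oracles for the compiled SPD geometry, plus fixture
# generators.  These deliberately use plain eigendecompositions (a different
# route than the package's Cholesky whitening) so the two act as mutual checks.

sym_pow <- function(S, p) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% diag(e$values^p, nrow(S)) %*% t(e$vectors)
}

sym_log <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% diag(log(e$values), nrow(S)) %*% t(e$vectors)
}

sym_exp <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% diag(exp(e$values), nrow(S)) %*% t(e$vectors)
}

# distance via direct eigendecomposition of B^{-1} A (independent route)
oracle_distance <- function(a, b) {
  ev <- eigen(solve(b, a), only.values = TRUE)$values
  sqrt(sum(log(Re(ev))^2))
}

# closed-form two-matrix geodesic midpoint
oracle_midpoint <- function(c1, c2) {
  h <- sym_pow(c1, 0.5)
  hi <- sym_pow(c1, -0.5)
  m <- h %*% sym_pow(hi %*% c2 %*% hi, 0.5) %*% h
  (m + t(m)) / 2
}

# log-Euclidean mean; exact geometric mean for commuting matrices
oracle_logeuclid_mean <- function(covs) {
  S <- Reduce(`+`, lapply(covs, sym_log)) / length(covs)
  sym_exp(S)
}

# brute-force reimplementation of the pre-rejection rule
oracle_prereject <- function(covs) {
  n <- length(covs)
  d <- numeric(n)
  for (i in seq_len(n)) {
    di <- 0
    for (j in seq_len(n)) {
      if (i != j) di <- di + riemann_distance(covs[[i]], covs[[j]])
    }
    d[i] <- di / (n - 1)
  }
  thr <- mean(d)
  list(kept = which(d <= thr), rejected = which(d > thr), d = d,
       threshold = thr)
}

random_spd <- function(n, scale = 1) {
  A <- matrix(rnorm(n * n), n)
  scale * (crossprod(A) / n + diag(n) * 0.1)
}

# cloud of SPD matrices around a center: C^{1/2} expm(r * U) C^{1/2} with a
# unit-Frobenius random symmetric direction U and lognormal radius r, so the
# affine-invariant distance to the center is exactly r (lognormal radially)
spd_cloud <- function(center, n_mats, spread = 0.2, sdlog = 0.25) {
  n <- nrow(center)
  h <- sym_pow(center, 0.5)
  lapply(seq_len(n_mats), function(i) {
    S <- matrix(rnorm(n * n), n)
    S <- (S + t(S)) / 2
    S <- S / sqrt(sum(S^2))
    r <- stats::rlnorm(1, meanlog = log(spread), sdlog = sdlog)
    m <- h %*% sym_exp(r * S) %*% h
    (m + t(m)) / 2
  })
}

# piecewise-constant trace for segmentation tests
flat_trace <- function(values, fs, step_samples = max(1L, round(0.1 * fs))) {
  structure(list(p_outlier = values, fs = fs, window_s = 1,
                 step_samples = as.integer(step_samples)),
            class = "rp_trace")
}

seg_tbl <- function(start_s, end_s, source = "expert") {
  tibble::tibble(start_s = start_s, end_s = end_s, source = source)
}

new_confusion_for_test <- function(tp, fp, tn, fn) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}
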