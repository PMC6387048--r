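# A tiny fitted model built directly from known distance statistics, so the
# scoring arithmetic can be checked without running the full fit.
toy_model <- function(centroid = diag(2) * 4, mu = 1, sigma = exp(1)) {
  stats <- structure(list(mu = mu, sigma = sigma, count = 100L),
                     class = "distance_stats")
  structure(list(centroids = list(centroid), stats = list(stats),
                 labels = NULL, k = 1L, combined_p = 1, cluster_p = 1,
                 member_distances = NULL, inertia = NULL,
                 n_channels = nrow(centroid), rejected_epochs = integer(0),
                 config = NULL, channel_names = NULL, fs = NULL, seed = NULL),
            class = "rp_model")
}

test_that("window scores map standardized distance through the Gaussian CDF", {
  set.seed(131)
  fs <- 100
  rec <- new_recording(matrix(rnorm(2 * 10 * fs, sd = 2), 2), fs)
  model <- toy_model()
  sc <- window_scores(rec, model, window_s = 1, step_fraction = 0.1)
  expect_true(all(sc$p_outlier >= 0 & sc$p_outlier <= 1))
  expect_true(all(diff(sc$center_sample) == 10))
  # a window whose covariance sits exactly mu from the centroid scores 0.5
  d <- riemann_distance(epoch_covariance(rec$signals[, 1:fs]), model$centroids[[1]])
  model2 <- toy_model(mu = d, sigma = exp(1))
  sc2 <- window_scores(rec, model2, window_s = 1, step_fraction = 0.1)
  expect_equal(sc2$p_outlier[1], 0.5, tolerance = 1e-12)
  # 1.6449 geometric SDs above the mean: p_outlier ~ 0.95
  model3 <- toy_model(mu = d / exp(1.6449), sigma = exp(1))
  sc3 <- window_scores(rec, model3, window_s = 1, step_fraction = 0.1)
  expect_equal(sc3$p_outlier[1], 0.95, tolerance = 1e-4)
  expect_error(window_scores(new_recording(matrix(rnorm(300), 3), 100), model),
               class = "rps_usage_error")
})

test_that("scoring a model's own training material gives calibrated probabilities", {
  set.seed(141)
  # distances standardize to ~N(0,1), so p = pnorm(z) should look uniform
  d <- exp(rnorm(500, mean = 0.5, sd = 0.3))
  st <- distance_stats(d)
  p <- pnorm(standardize_distance(d, st))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(median(p), 0.5, tolerance = 0.1)
})

test_that("trace interpolation follows the documented anchor scheme", {
  fs <- 100
  # single anchor at the midpoint: triangular ramp 0 -> 1 -> 0
  tr <- build_trace(tibble::tibble(center_sample = 50, p_outlier = 1),
                    rec_length = 100, fs = fs)
  expect_length(tr$p_outlier, 100)
  expect_equal(tr$p_outlier[1], 0)
  expect_equal(tr$p_outlier[100], 0)
  expect_equal(tr$p_outlier[50], 1)
  expect_equal(tr$p_outlier[25], (25 - 1) / 49, tolerance = 1e-10)
  # constant anchors every 0.1 s: flat interior, tapering only at the ends
  centers <- seq(10, 90, by = 10)
  tr2 <- build_trace(tibble::tibble(center_sample = centers,
                                    p_outlier = rep(0.7, length(centers))),
                     rec_length = 100, fs = fs)
  expect_true(all(abs(tr2$p_outlier[10:90] - 0.7) < 1e-12))
  expect_lt(tr2$p_outlier[5], 0.7)
  # midpoint between two anchors
  tr3 <- build_trace(tibble::tibble(center_sample = c(100, 200),
                                    p_outlier = c(0.2, 0.8)),
                     rec_length = 300, fs = fs)
  expect_equal(tr3$p_outlier[150], 0.5, tolerance = 1e-10)
  expect_error(build_trace(tibble::tibble(center_sample = numeric(0),
                                          p_outlier = numeric(0)), 100, fs),
               class = "rps_usage_error")
})

test_that("moving-average smoothing has the expected impulse and range behaviour", {
  fs <- 100
  const <- flat_trace(rep(0.4, 500), fs)
  expect_equal(smooth_trace(const, 0.5)$p_outlier, rep(0.4, 500))
  imp <- flat_trace(c(rep(0, 250), 1, rep(0, 249)), fs)
  sm <- smooth_trace(imp, 0.5)  # 50-sample window
  expect_equal(max(sm$p_outlier), 1 / 50, tolerance = 1e-12)
  expect_equal(sum(sm$p_outlier > 0), 50)
  set.seed(151)
  for (rep_i in 1:5) {
    x <- runif(300)
    tr <- flat_trace(x, fs)
    sm <- smooth_trace(tr, runif(1, 0.1, 1))
    expect_lte(max(sm$p_outlier), max(x) + 1e-12)
    expect_gte(min(sm$p_outlier), 0)
  }
})

test_that("minimum-duration rule gates supra-threshold runs at 0.4 s", {
  fs <- 250
  base <- rep(0.1, 3 * fs)
  # 0.39 s above threshold: no artifact
  x <- base; x[301:(300 + 97)] <- 0.99   # 97 samples < 0.4 * 250 = 100
  expect_equal(nrow(segment_and_threshold(flat_trace(x, fs), 0.95, 0.4)), 0)
  # 0.50 s above threshold: exactly one artifact covering the run
  y <- base; y[301:(300 + 125)] <- 0.99
  segs <- segment_and_threshold(flat_trace(y, fs), 0.95, 0.4)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_s, 300 / fs)
  expect_equal(segs$end_s, 425 / fs)
  expect_equal(segs$peak_score, 0.99)
})

test_that("local minima split humps into separate artifacts", {
  fs <- 100
  hump <- function(len, peak) peak * sin(pi * seq_len(len) / (len + 1))
  x <- c(rep(0, 50), hump(150, 0.99), rep(0.05, 30), hump(150, 0.99), rep(0, 50))
  segs <- segment_and_threshold(flat_trace(x, fs), 0.5, 0.4)
  expect_equal(nrow(segs), 2)
  expect_true(all(segs$end_s - segs$start_s >= 0.4))
  # brute-force check: all reported samples are supra-threshold
  m <- segments_to_mask(segs, length(x) / fs, fs)
  expect_true(all(x[m] > 0.5))
})

test_that("raising the threshold never increases total flagged duration", {
  set.seed(161)
  fs <- 100
  x <- pmin(1, pmax(0, stats::filter(runif(2000), rep(1 / 30, 30), sides = 2)))
  x[is.na(x)] <- 0
  tr <- flat_trace(as.numeric(x), fs)
  total <- function(th) {
    s <- segment_and_threshold(tr, th, 0.2)
    sum(s$end_s - s$start_s)
  }
  durs <- vapply(c(0.3, 0.5, 0.7, 0.9), total, numeric(1))
  expect_true(all(diff(durs) <= 1e-9))
})

test_that("end-to-end detection flags injected bursts and little else", {
  set.seed(171)
  # model fitted on a normal (artifact-bearing) recording, then applied to a
  # clean recording from the same regime: few false alarms expected
  spec_train <- default_sleep_spec(n_channels = 4, fs = 100, duration_s = 180,
                                   seed = 11, n_regimes = 1)
  cfg <- rp_config(seed = 3L, k_max = 4L)
  model <- rp_fit(synth_generate(spec_train)$recording, cfg)
  spec_clean <- default_sleep_spec(n_channels = 4, fs = 100, duration_s = 180,
                                   seed = 19, artifact_scale = 0, n_regimes = 1)
  syn <- synth_generate(spec_clean)
  det <- rp_detect(syn$recording, model, cfg)
  flagged <- sum(det$segments$end_s - det$segments$start_s)
  expect_lte(flagged / 180, 0.05)
  # same regimes with bursts injected: most bursts overlap a detection
  spec2 <- default_sleep_spec(n_channels = 4, fs = 100, duration_s = 180,
                              seed = 12, n_regimes = 1)
  spec2$artifact_plan <- spec2$artifact_plan[spec2$artifact_plan$type == "burst", ]
  spec2$artifact_plan$rate_per_min <- 10 / 3  # ten 1-3 s bursts in 3 min
  syn2 <- synth_generate(spec2)
  model2 <- rp_fit(syn2$recording, cfg)
  det2 <- rp_detect(syn2$recording, model2, cfg)
  truth <- syn2$artifact_segments
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(det2$segments$start_s < truth$end_s[i] &
          det2$segments$end_s > truth$start_s[i])
  }, logical(1))
  expect_gte(mean(hit), 0.8)
  # channel mismatch propagates as usage error
  bad <- new_recording(matrix(rnorm(3 * 500), 3), 100)
  expect_error(rp_detect(bad, model, cfg), class = "rps_usage_error")
  # an all-zero recording has rank-deficient window covariances
  flat <- new_recording(matrix(0, 4, 2000), 100)
  expect_error(rp_detect(flat, model, cfg), class = "rps_invalid_matrix")
})

test_that("detection output segments are disjoint, sorted and long enough", {
  set.seed(181)
  fs <- 100
  x <- rep(0.2, 5000)
  for (s in c(500, 1500, 3000, 4200)) x[s:(s + 199)] <- 0.99
  segs <- segment_and_threshold(flat_trace(x, fs), 0.9, 0.4)
  expect_true(all(diff(segs$start_s) > 0))
  expect_true(all(segs$start_s[-1] >= segs$end_s[-nrow(segs)]))
  expect_true(all(segs$end_s - segs$start_s >= 0.4 - 1e-9))
})
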