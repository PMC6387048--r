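test_that("pre-rejection matches the brute-force rule and its edge cases", {
  set.seed(61)
  # far outlier: one epoch much farther than a tight cloud near identity
  covs <- c(spd_cloud(diag(3), 9, spread = 0.05),
            list(diag(exp(c(10, 9, 8)))))
  pre <- prereject_outliers(covs)
  expect_equal(pre$rejected, 10L)
  expect_setequal(pre$kept, 1:9)
  # identical matrices: all kept (threshold 0, nothing strictly greater)
  same <- replicate(10, diag(2), simplify = FALSE)
  pre2 <- prereject_outliers(same)
  expect_length(pre2$rejected, 0)
  expect_equal(pre2$threshold, 0)
  # random sets agree exactly with an independent O(N^2) reimplementation
  for (rep in 1:5) {
    covs <- spd_cloud(random_spd(3), sample(5:20, 1), spread = 0.6)
    got <- prereject_outliers(covs)
    want <- oracle_prereject(covs)
    expect_equal(got$kept, want$kept)
    expect_equal(got$rejected, want$rejected)
    expect_equal(got$d, want$d, tolerance = 1e-10)
  }
  expect_error(prereject_outliers(list(diag(2))), class = "rps_usage_error")
})

test_that("k-means with k = 1 returns the geometric mean; k > N errors", {
  set.seed(71)
  covs <- spd_cloud(random_spd(3), 12, spread = 0.3)
  km <- riemann_kmeans(covs, 1, seed = 4)
  expect_equal(km$labels, rep(1L, 12))
  expect_equal(km$centroids[[1]], unclass(geometric_mean(covs)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(riemann_kmeans(covs, 13, seed = 1), class = "rps_usage_error")
})

test_that("k-means separates two well-separated families and is deterministic", {
  set.seed(81)
  fam1 <- spd_cloud(diag(4), 15, spread = 0.2)
  fam2 <- spd_cloud(diag(exp(c(4, 4, -4, -4))), 15, spread = 0.2)
  covs <- c(fam1, fam2)
  truth <- rep(1:2, each = 15)
  km <- riemann_kmeans(covs, 2, seed = 9)
  # labels match the generating families up to relabeling
  agree <- max(mean(km$labels == truth), mean(km$labels == 3 - truth))
  expect_equal(agree, 1)
  km2 <- riemann_kmeans(covs, 2, seed = 9)
  expect_identical(km$labels, km2$labels)
  expect_equal(km$inertia, km2$inertia)
  # inertia trace is non-increasing
  expect_true(all(diff(km$inertia_trace) <= 1e-8))
  # member distance bookkeeping
  for (j in 1:2) {
    expect_length(km$member_distances[[j]], sum(km$labels == j))
  }
})

test_that("inertia never increases over iterations on heterogeneous input", {
  set.seed(91)
  covs <- c(spd_cloud(diag(3), 10, 0.5),
            spd_cloud(diag(exp(c(2, 0, -2))), 10, 0.5),
            spd_cloud(random_spd(3), 10, 0.5))
  for (k in c(2, 3, 4)) {
    km <- riemann_kmeans(covs, k, seed = k)
    expect_true(all(diff(km$inertia_trace) <= 1e-8))
  }
})

test_that("combined normality p-value behaves under null, alternative and fixed points", {
  set.seed(101)
  # lognormal distances: ln(d) Gaussian, so standardized distances pass K2
  p_null <- replicate(20, {
    d <- exp(rnorm(500, sd = 0.4))
    cluster_normality_p(list(member_distances = list(d)))
  })
  expect_gt(mean(p_null > 0.05), 0.85)
  # strongly bimodal ln(d): K2 rejects
  p_alt <- replicate(10, {
    d <- exp(c(rnorm(250, -2, 0.2), rnorm(250, 2, 0.2)))
    cluster_normality_p(list(member_distances = list(d)))
  })
  expect_true(all(p_alt < 0.05))
  # undersized cluster invalidates the configuration
  expect_equal(cluster_normality_p(list(member_distances =
    list(exp(rnorm(500)), exp(rnorm(5))))), 0)
})

test_that("cluster-count selection recovers simple regime structure", {
  set.seed(111)
  # one tight lognormal-ish cloud: a single cluster suffices
  covs1 <- spd_cloud(diag(3), 120, spread = 0.15)
  m1 <- select_cluster_count(covs1, k_max = 4, seed = 2)
  expect_equal(m1$k, 1)
  expect_gt(m1$combined_p, 0.05)
  # three well-separated families at distinct radii (scalene geometry with a
  # dominant family, the regime the selection rule is built for)
  centers <- list(diag(4), diag(exp(c(5, 5, -5, -5))), diag(exp(c(-7, 7, -7, 3))))
  sizes <- c(80, 60, 45)
  covs3 <- unlist(lapply(1:3, function(j)
    spd_cloud(centers[[j]], sizes[j], spread = 0.15)), recursive = FALSE)
  m3 <- select_cluster_count(covs3, k_max = 6, seed = 2, min_cluster_size = 20)
  expect_equal(m3$k, 3)
  # k_max honoured on the same input
  m2 <- select_cluster_count(covs3, k_max = 2, seed = 2)
  expect_lte(m2$k, 2)
  # per-cluster stats counts match the labels
  for (j in seq_len(m3$k)) {
    expect_equal(m3$stats[[j]]$count, sum(m3$labels == j))
  }
  expect_error(select_cluster_count(spd_cloud(diag(2), 5), k_max = 2),
               class = "rps_usage_error")
})

test_that("model JSON serialization round-trips centroids and statistics", {
  set.seed(121)
  covs <- c(spd_cloud(diag(3), 40, 0.2),
            spd_cloud(diag(exp(c(4, 0, -4))), 40, 0.2))
  model <- select_cluster_count(covs, k_max = 3, seed = 5)
  model$config <- rp_config(seed = 5L)
  model$channel_names <- c("C3", "C4", "Cz")
  model$fs <- 100
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$k, model$k)
  expect_equal(back$n_channels, 3)
  for (j in seq_len(model$k)) {
    expect_equal(back$centroids[[j]], model$centroids[[j]], tolerance = 1e-12)
    expect_equal(back$stats[[j]]$mu, model$stats[[j]]$mu)
    expect_equal(back$stats[[j]]$sigma, model$stats[[j]]$sigma)
  }
  expect_equal(back$combined_p, model$combined_p)
  expect_equal(back$channel_names, model$channel_names)
  expect_equal(back$config$threshold, model$config$threshold)
})
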