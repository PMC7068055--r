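test_that("observation matrices have participant x condition x electrode rows", {
  co <- simulate_average_cohort(4L, seed = 1, fs = 250,
                                channels = recovery_channels())
  om <- build_observation_matrix(co, "eeg", scope = "adults")
  expect_equal(nrow(om$X), 4 * 3 * 9)
  expect_equal(ncol(om$X), length(co$time_eeg))
  om_p <- build_observation_matrix(co, "pupil", scope = "pooled")
  expect_equal(nrow(om_p$X), 8 * 3)
  # degenerate: a single observation
  co1 <- co
  co1$eeg <- co$eeg[1, 1, 1, , drop = FALSE]
  co1$subjects <- co$subjects[1, , drop = FALSE]
  co1$channels <- co$channels[1]
  co1$conditions <- co$conditions[1]
  expect_error(build_observation_matrix(co1, "eeg"), "degenerate")
})

test_that("Horn's parallel test retains planted rank and ignores duplication", {
  set.seed(10)
  n <- 150; p <- 30
  noise_only <- matrix(rnorm(n * p), n, p)
  # under the conservative 95th-percentile rule pure noise retains nothing
  ks <- vapply(1:20, function(s)
    as.integer(horns_parallel_test(noise_only, quantile_rule = 0.95,
                                   seed = s)), integer(1))
  expect_gte(mean(ks <= 1), 0.95)
  planted <- matrix(rnorm(n * 3), n, 3) %*%
    (matrix(runif(3 * p, -1, 1), 3, p) * 3) + matrix(rnorm(n * p), n, p)
  expect_equal(as.integer(horns_parallel_test(planted, seed = 4)), 3L)
  doubled <- rbind(planted, planted)
  expect_equal(as.integer(horns_parallel_test(doubled, seed = 4)), 3L)
  expect_error(horns_parallel_test(planted, n_surrogates = 10), ">= 50")
})

test_that("geomin criterion matches a grid-search oracle for K = 2", {
  set.seed(21)
  a <- cbind(c(rep(0.8, 6), rep(0.05, 6)) + rnorm(12, 0, 0.05),
             c(rep(0.05, 6), rep(0.7, 6)) + rnorm(12, 0, 0.05))
  mixed <- a %*% matrix(c(0.9, 0.5, -0.4, 1.1), 2, 2)
  res <- geomin_rotate(mixed, epsilon = 0.5, n_starts = 20, seed = 2)
  oracle <- geomin_grid_oracle(mixed, 0.5)
  expect_equal(res$criterion, oracle, tolerance = 1e-4)
  expect_equal(diag(res$Phi), c(1, 1), tolerance = 1e-10)
})

test_that("geomin is permutation-symmetric, eps-dominated, K=1 passthrough", {
  set.seed(22)
  a <- matrix(rnorm(30), 15, 2)
  r1 <- geomin_rotate(a, 0.5, n_starts = 10, seed = 1)
  r2 <- geomin_rotate(a[, 2:1], 0.5, n_starts = 10, seed = 1)
  expect_equal(r1$criterion, r2$criterion, tolerance = 1e-6)
  # eps >> loadings: criterion insensitive to rotation
  big <- vapply(1:5, function(s) {
    geomin_rotate(a, 1e6, n_starts = 2, seed = s)$criterion
  }, numeric(1))
  expect_lt(diff(range(big)) / big[1], 1e-6)
  one <- geomin_rotate(a[, 1, drop = FALSE], 0.5)
  expect_identical(one$loadings, a[, 1, drop = FALSE])
})

test_that("rotating an already optimal solution leaves the criterion fixed", {
  set.seed(23)
  a <- cbind(c(rep(1, 8), rep(0, 8)), c(rep(0, 8), rep(1, 8))) +
    matrix(rnorm(32, 0, 0.02), 16, 2)
  r1 <- geomin_rotate(a, 0.5, n_starts = 15, seed = 3, tol = 1e-12)
  # refitting from the converged rotation is idempotent
  r2 <- geomin_rotate(a, 0.5, n_starts = 0, T_init = r1$Tmat, tol = 1e-12)
  expect_equal(r2$criterion, r1$criterion, tolerance = 1e-10)
  expect_equal(r2$loadings, r1$loadings, tolerance = 1e-3)
  # the reported criterion is the geomin value of the returned loadings
  k2 <- ncol(r1$loadings)
  expect_equal(r1$criterion,
               sum(exp(rowMeans(log(r1$loadings^2 + 0.5)))),
               tolerance = 1e-12)
})

test_that("full-rank reconstruction identity holds to 1e-8", {
  set.seed(30)
  x <- matrix(rnorm(40 * 10), 40, 10)
  om <- toy_observation_matrix(x)
  f <- fit_temporal_pca(om, K = 10, n_starts = 5, seed = 2)
  rec <- f$scores %*% t(f$loadings_scaled) + rep(f$mu, each = 40)
  expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-8)
  expect_error(fit_temporal_pca(om, K = 11), "rank")
  # explained variance: in [0, 1], non-increasing
  expect_true(all(f$explained_variance >= 0 & f$explained_variance <= 1))
  expect_true(all(diff(f$explained_variance) <= 1e-12))
  # factor correlation matrix is a correlation matrix
  expect_equal(diag(f$Phi), rep(1, 10), tolerance = 1e-8)
  expect_equal(f$Phi, t(f$Phi), tolerance = 1e-10)
})

test_that("planted non-overlapping kernels are recovered by the rotation", {
  set.seed(31)
  t_ms <- seq(0, 796, 4)
  k1 <- erp_kernel(t_ms, 150, 25)
  k2 <- erp_kernel(t_ms, 500, 40)
  amps <- cbind(abs(rnorm(120, 4)), abs(rnorm(120, 3)))
  x <- amps %*% rbind(k1, k2) + matrix(rnorm(120 * length(t_ms), 0, 0.05),
                                       120)
  om <- toy_observation_matrix(x, time_ms = t_ms, fs = 250)
  f <- fit_temporal_pca(om, K = 2, n_starts = 15, seed = 3)
  cors <- abs(stats::cor(f$loadings_scaled, cbind(k1, k2)))
  expect_true(all(apply(cors, 2, max) > 0.99))
})

test_that("geomin solutions are invariant to global row scaling", {
  set.seed(32)
  x <- matrix(rnorm(60 * 12), 60, 12)
  om1 <- toy_observation_matrix(x)
  om2 <- toy_observation_matrix(10 * x)
  f1 <- fit_temporal_pca(om1, K = 3, n_starts = 10, seed = 1)
  f2 <- fit_temporal_pca(om2, K = 3, n_starts = 10, seed = 1)
  expect_equal(f2$loadings_scaled, 10 * f1$loadings_scaled,
               tolerance = 1e-6)
  expect_equal(f2$explained_variance, f1$explained_variance,
               tolerance = 1e-10)
})

test_that("component time courses reconstruct scores x loadings", {
  set.seed(33)
  x <- matrix(rnorm(30 * 8), 30, 8)
  om <- toy_observation_matrix(x)
  f <- fit_temporal_pca(om, K = 8, n_starts = 3, seed = 1)
  # zero score -> zero time course
  f0 <- f; f0$scores[1, 2] <- 0
  tc <- reconstruct_component_timecourse(f0, 2, subject = 1)
  expect_true(all(tc == 0))
  # sum over all components restores the centered waveform
  total <- Reduce(`+`, lapply(1:8, function(k)
    reconstruct_component_timecourse(f, k, subject = 5)))
  expect_equal(total, x[5, ] - f$mu, tolerance = 1e-8)
  expect_error(reconstruct_component_timecourse(f, 9), "component")
  expect_error(reconstruct_component_timecourse(f, 1, subject = 99),
               "unknown")
})
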