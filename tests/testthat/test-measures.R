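test_that("templates map to the planted components", {
  co <- simulate_average_cohort(8L, seed = 3, fs = 250,
                                channels = recovery_channels())
  om <- build_observation_matrix(co, "eeg", scope = "adults")
  f <- fit_temporal_pca(om, K = 8, n_starts = 10, seed = 2)
  tpl <- component_templates("eeg")
  asg <- identify_components(f, tpl[tpl$name == "eP3a", ])
  expect_false(is.na(asg["eP3a"]))
  pk <- f$time_ms[which.max(abs(f$loadings_scaled[, asg["eP3a"]]))]
  expect_gte(pk, 180); expect_lte(pk, 340)
  # pupil: early and late components map respectively
  om_p <- build_observation_matrix(co, "pupil", scope = "pooled")
  f_p <- fit_temporal_pca(om_p, K = 2, n_starts = 10, seed = 2)
  asg_p <- identify_components(f_p, component_templates("pupil"))
  expect_false(any(is.na(asg_p)))
  pk_e <- f_p$time_ms[which.max(abs(f_p$loadings_scaled[, asg_p["PDR_early"]]))]
  pk_l <- f_p$time_ms[which.max(abs(f_p$loadings_scaled[, asg_p["PDR_late"]]))]
  expect_lt(pk_e, pk_l)
  expect_equal(pk_e, 640, tolerance = 200)
  expect_equal(pk_l, 1520, tolerance = 250)
})

test_that("no-match and ambiguity paths behave as specified", {
  set.seed(5)
  x <- matrix(rnorm(40 * 20), 40, 20)
  om <- toy_observation_matrix(x, fs = 100)   # time 0..190 ms
  f <- fit_temporal_pca(om, K = 1, n_starts = 2, seed = 1)
  tpl <- data.frame(name = "late", window_lo = 1000, window_hi = 1500,
                    polarity = 1, electrode = "Cz",
                    stringsAsFactors = FALSE)
  asg <- identify_components(f, tpl)
  expect_true(is.na(asg["late"]))             # reported, no error
  # two templates claiming one component: error, or greedy resolution
  t_ms <- seq(0, 396, 4)
  k1 <- erp_kernel(t_ms, 150, 30)
  amp <- c(abs(rnorm(25, 5)), abs(rnorm(25, 1)))   # novels load higher
  x2 <- cbind(amp) %*% rbind(k1) +
    matrix(rnorm(50 * length(t_ms), 0, 0.01), 50)
  lab2 <- data.frame(subject = 1:50, group = "g",
                     condition = rep(c("novel_neutral", "standard"),
                                     each = 25),
                     electrode = "Cz", stringsAsFactors = FALSE)
  om2 <- toy_observation_matrix(x2, time_ms = t_ms, fs = 250,
                                labels = lab2)
  f2 <- fit_temporal_pca(om2, K = 1, n_starts = 1, seed = 1)
  tpl2 <- data.frame(name = c("a", "b"),
                     window_lo = c(100, 120), window_hi = c(200, 220),
                     polarity = 1, electrode = "Cz",
                     stringsAsFactors = FALSE)
  expect_error(identify_components(f2, tpl2), "same component")
  asg2 <- identify_components(f2, tpl2, resolve_ambiguity = TRUE)
  expect_equal(sum(!is.na(asg2)), 1L)
})

test_that("mean amplitude integrates the stated window", {
  t_ms <- seq(0, 500, 2)
  expect_equal(mean_amplitude(rep(3.5, length(t_ms)), t_ms, 250), 3.5)
  expect_equal(mean_amplitude(numeric(length(t_ms)), t_ms, 250), 0)
  # symmetric triangular peak: closed-form mean of the sampled triangle
  h <- 6; center <- 250; base_hw <- 40
  tri <- pmax(0, h * (1 - abs(t_ms - center) / base_hw))
  idx <- which(t_ms >= 230 & t_ms <= 270)
  expect_equal(mean_amplitude(tri, t_ms, 250, 20), mean(tri[idx]))
  # near the continuous-integral value h * 3/4 at this sampling density
  expect_equal(mean_amplitude(tri, t_ms, 250, 20), h * 0.75,
               tolerance = 0.1)
  expect_error(mean_amplitude(tri, t_ms, 10, 20), "clipped")
})

test_that("difference amplitudes subtract standard from novel", {
  expect_equal(difference_amplitude(2.0, 0.5), 1.5)
  expect_equal(difference_amplitude(1.1, 1.1), 0)
})

test_that("planted emotion and group amplitude effects are recovered", {
  co <- simulate_average_cohort(12L, seed = 7, fs = 250,
                                channels = recovery_channels())
  tpl <- component_templates("eeg")
  diffs <- list()
  for (g in c("adults", "children")) {
    om <- build_observation_matrix(co, "eeg", scope = g)
    f <- fit_temporal_pca(om, K = 8, n_starts = 10, seed = 2)
    k <- identify_components(f, tpl[tpl$name == "eP3a", ])["eP3a"]
    amps <- component_amplitudes(f, k, electrode = "Cz")
    diffs[[g]] <- amps
  }
  truth_a <- default_ground_truth("adults")$erp
  truth_a <- truth_a[truth_a$name == "eP3a", ]
  emo <- diffs$adults$difference[diffs$adults$condition == "novel_emotional"]
  neu <- diffs$adults$difference[diffs$adults$condition == "novel_neutral"]
  # recovered novelty difference near the planted one (PCA splits some
  # variance with neighbours; generous tolerance)
  expect_equal(mean(neu),
               truth_a$amp_novel_neutral - truth_a$amp_standard,
               tolerance = 0.35 * truth_a$amp_novel_neutral)
  # emotion effect has the planted sign
  expect_gt(mean(emo) - mean(neu), 0)
  # group effect has the planted sign (children larger)
  neu_c <- diffs$children$difference[
    diffs$children$condition == "novel_neutral"]
  expect_gt(mean(neu_c), mean(neu))
})

test_that("jackknife pseudo-values satisfy their identities", {
  # identical subjects: degenerate jackknife
  t_ms <- seq(0, 796, 4)
  kern <- erp_kernel(t_ms, 230, 30)
  n_sub <- 5
  rows <- do.call(rbind, replicate(n_sub, {
    rbind(4 * kern, 5 * kern, 6 * kern)
  }, simplify = FALSE))
  rows <- rows + matrix(rnorm(length(rows), 0, 1e-4), nrow(rows))
  labels <- data.frame(subject = rep(1:n_sub, each = 3),
                       group = "g",
                       condition = rep(c("standard", "novel_neutral",
                                         "novel_emotional"), n_sub),
                       electrode = "Cz", stringsAsFactors = FALSE)
  om <- toy_observation_matrix(rows, time_ms = t_ms, fs = 250,
                               labels = labels)
  tpl <- component_templates("eeg")
  jl <- jackknife_latencies(om, K = 1, tpl[tpl$name == "eP3a", ],
                            n_starts_full = 1, seed = 1)
  expect_equal(unname(jl$loo), rep(jl$theta_full, n_sub),
               tolerance = 1e-3)
  expect_equal(unname(jl$retrieved), rep(jl$theta_full, n_sub),
               tolerance = 0.05)
  # pseudo-value identity holds exactly by construction
  expect_equal(mean(jl$retrieved),
               jl$n * jl$theta_full - (jl$n - 1) * mean(jl$loo),
               tolerance = 1e-12)
})

test_that("n = 3 jackknife matches direct pseudo-value arithmetic", {
  # single component, subject-specific latencies; independent oracle uses
  # eigen() + the criterion rule directly
  t_ms <- seq(0, 796, 4)
  # amplitude variation dominates, small latency spread: loadings unimodal
  lats <- c(226, 230, 234)
  amps <- c(2, 5, 9)
  rows <- do.call(rbind, lapply(1:3, function(i) {
    rbind(0.8 * amps[i] * erp_kernel(t_ms, lats[i], 30),
          1.2 * amps[i] * erp_kernel(t_ms, lats[i], 30))
  }))
  labels <- data.frame(subject = rep(1:3, each = 2), group = "g",
                       condition = rep(c("novel_neutral",
                                         "novel_emotional"), 3),
                       electrode = "Cz", stringsAsFactors = FALSE)
  om <- toy_observation_matrix(rows, time_ms = t_ms, fs = 250,
                               labels = labels)
  tpl <- component_templates("eeg")
  jl <- jackknife_latencies(om, K = 1, tpl[tpl$name == "eP3a", ],
                            n_starts_full = 1, seed = 1)
  oracle_theta <- function(x) {
    eg <- eigen(stats::cov(x), symmetric = TRUE)
    ld <- eg$vectors[, 1] * sqrt(eg$values[1])
    if (ld[which.max(abs(ld))] < 0) ld <- -ld
    win <- t_ms >= 180 & t_ms <= 340
    lv <- ld[win]; tv <- t_ms[win]
    thr <- 0.8 * max(lv)
    i <- which(lv >= thr)[1]
    if (i == 1) return(tv[1])
    tv[i - 1] + (thr - lv[i - 1]) / (lv[i] - lv[i - 1]) * 4
  }
  th <- oracle_theta(rows)
  loo <- vapply(1:3, function(i)
    oracle_theta(rows[labels$subject != i, ]), numeric(1))
  expect_equal(jl$theta_full, th, tolerance = 1e-6)
  expect_equal(unname(jl$retrieved), 3 * th - 2 * loo, tolerance = 1e-6)
})

test_that("latency estimates ignore global amplitude scaling", {
  co <- simulate_average_cohort(6L, seed = 2, fs = 250,
                                channels = recovery_channels())
  om <- build_observation_matrix(co, "eeg", scope = "adults")
  om2 <- om; om2$X <- om$X * 7; om2$mu <- om$mu * 7; om2$sd <- om$sd * 7
  tpl <- component_templates("eeg")
  j1 <- jackknife_latencies(om, K = 6, tpl[tpl$name == "eP3a", ], seed = 4,
                            n_starts_full = 5)
  j2 <- jackknife_latencies(om2, K = 6, tpl[tpl$name == "eP3a", ], seed = 4,
                            n_starts_full = 5)
  expect_equal(j1$theta_full, j2$theta_full, tolerance = 1e-6)
  expect_equal(j1$retrieved, j2$retrieved, tolerance = 1e-4)
})

test_that("pseudo-value variance is (n-1)^2 times leave-one-out variance", {
  co <- simulate_average_cohort(8L, seed = 6, fs = 250,
                                channels = recovery_channels())
  om <- build_observation_matrix(co, "eeg", scope = "children")
  tpl <- component_templates("eeg")
  jl <- jackknife_latencies(om, K = 8, tpl[tpl$name == "eP3a", ], seed = 2,
                            n_starts_full = 5)
  expect_equal(stats::var(jl$retrieved),
               (jl$n - 1)^2 * stats::var(jl$loo), tolerance = 1e-9)
})
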