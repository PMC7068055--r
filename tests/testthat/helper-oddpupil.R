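# shared fixtures, all generated in code

# compact montage for fast end-to-end runs
small_montage <- function() {
  m <- default_montage()
  m[m$channel %in% c("Fp1", "Fp2", "Fz", "Cz", "Pz", "F3", "F4", "C3",
                     "C4", "Oz", "HEOG_L", "HEOG_R", "VEOG"), ]
}

# nine-electrode channel set used by the recovery simulations
recovery_channels <- function() {
  c("Fz", "Cz", "Pz", "F3", "F4", "C3", "C4", "Fp1", "Oz")
}

small_design <- function(blocks = 2L, trials = 40L, novels = 4L) {
  design_config(blocks = blocks, trials_per_block = trials,
                novels_emotional = novels, novels_neutral = novels)
}

# wrap a plain matrix as an observation_matrix
toy_observation_matrix <- function(x, time_ms = NULL, fs = 100,
                                   labels = NULL) {
  if (is.null(time_ms)) time_ms <- (seq_len(ncol(x)) - 1) * 1000 / fs
  if (is.null(labels))
    labels <- data.frame(subject = seq_len(nrow(x)), group = "g",
                         condition = "novel_neutral", electrode = "Cz",
                         stringsAsFactors = FALSE)
  structure(list(X = x, labels = labels, time_ms = time_ms,
                 mu = colMeans(x), sd = apply(x, 2, stats::sd), fs = fs),
            class = "observation_matrix")
}

# independent brute-force sums-of-squares oracle for the 2 x 2 mixed design
# (one between factor g, one within factor w, balanced)
brute_force_mixed_anova <- function(d) {
  # d: subject, g, w, y
  mu <- mean(d$y)
  n_s <- length(unique(d$subject))
  cell <- function(expr) with(d, expr)
  ss_total <- sum((d$y - mu)^2)
  subj_mean <- tapply(d$y, d$subject, mean)
  g_of_subj <- tapply(as.character(d$g), d$subject, `[`, 1)
  g_mean <- tapply(d$y, d$g, mean)
  w_mean <- tapply(d$y, d$w, mean)
  gw_mean <- tapply(d$y, list(d$g, d$w), mean)
  n_w <- length(unique(d$w))
  n_g <- length(unique(d$g))
  n_per_g <- n_s / n_g
  ss_g <- n_w * n_per_g * sum((g_mean - mu)^2)
  ss_subj <- n_w * sum((subj_mean - g_mean[g_of_subj])^2)
  ss_w <- n_s * sum((w_mean - mu)^2)
  ss_gw <- n_per_g * sum((t(gw_mean) - outer(w_mean, rep(1, n_g)) -
                            outer(rep(1, n_w), g_mean) + mu)^2)
  ss_err <- ss_total - ss_g - ss_subj - ss_w - ss_gw
  df_g <- n_g - 1; df_subj <- n_s - n_g
  df_w <- n_w - 1; df_gw <- df_g * df_w; df_err <- df_subj * df_w
  list(
    F_g = (ss_g / df_g) / (ss_subj / df_subj),
    F_w = (ss_w / df_w) / (ss_err / df_err),
    F_gw = (ss_gw / df_gw) / (ss_err / df_err),
    eta_g = ss_g / ss_total, eta_w = ss_w / ss_total,
    eta_gw = ss_gw / ss_total,
    df = c(df_g, df_subj, df_w, df_gw, df_err)
  )
}

# fine-grid quadrature oracle for the JZS Bayes factor
jzs_bf_quadrature <- function(t, n_eff, nu, r = sqrt(2) / 2,
                              n_grid = 200000L) {
  # integrate over u = g / (1 + g) on a uniform fine grid
  u <- (seq_len(n_grid) - 0.5) / n_grid
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  log_prior <- 0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
    r^2 / (2 * g)
  log_lik1 <- -0.5 * log1p(n_eff * g) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + n_eff * g) * nu))
  log_lik0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  sum(exp(log_lik1 + log_prior - log_lik0) * jac) / n_grid
}

# brute-force geomin minimum over oblique transforms for K = 2:
# T columns are unit vectors at angles (a, b); coarse grid then local
# refinement around the best grid point
geomin_grid_oracle <- function(A, epsilon) {
  crit <- function(ang) {
    Tm <- cbind(c(cos(ang[1]), sin(ang[1])), c(cos(ang[2]), sin(ang[2])))
    if (abs(det(Tm)) < 1e-6) return(Inf)
    L <- A %*% t(solve(Tm))
    sum(exp(rowMeans(log(L^2 + epsilon))))
  }
  grid <- seq(0, pi, length.out = 181)  # 1 degree
  best <- c(0, pi / 2); best_f <- Inf
  for (a in grid) for (b in grid) {
    f <- crit(c(a, b))
    if (f < best_f) { best_f <- f; best <- c(a, b) }
  }
  step <- pi / 180
  for (refine in 1:4) {
    fine_a <- seq(best[1] - step, best[1] + step, length.out = 21)
    fine_b <- seq(best[2] - step, best[2] + step, length.out = 21)
    for (a in fine_a) for (b in fine_b) {
      f <- crit(c(a, b))
      if (f < best_f) { best_f <- f; best <- c(a, b) }
    }
    step <- step / 10
  }
  best_f
}
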