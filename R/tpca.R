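#' Build the observation matrix for temporal PCA
#'
#' Time points are variables (columns); observations (rows) are every
#' combination of participant, condition and electrode for ERP data, or
#' participant and condition for pupil data. ERP decompositions are fitted
#' separately per group (the component structure differs between children
#' and adults); the pupil decomposition pools both groups.
#'
#' @param cohort an `average_cohort`.
#' @param modality `"eeg"` or `"pupil"`.
#' @param scope `"pooled"` or a group label to restrict rows to.
#' @return An `observation_matrix`: `X` (rows x time), `labels` data frame
#'   (`subject`, `group`, `condition`, `electrode`), `time_ms`, `mu` and
#'   `sd` per column, `fs`.
#' @export
build_observation_matrix <- function(cohort,
                                     modality = c("eeg", "pupil"),
                                     scope = "pooled") {
  modality <- match.arg(modality)
  subj <- cohort$subjects
  keep <- if (identical(scope, "pooled")) rep(TRUE, nrow(subj))
          else subj$group == scope
  if (!any(keep)) stopf("no subjects in scope '%s'", scope)
  ids <- which(keep)
  conds <- cohort$conditions
  if (modality == "eeg") {
    chans <- cohort$channels
    labels <- expand.grid(electrode = chans, condition = conds,
                          subject = subj$subject[ids],
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    x <- matrix(NA_real_, nrow(labels), length(cohort$time_eeg))
    r <- 0L
    for (i in ids) for (ci in seq_along(conds)) for (ei in seq_along(chans)) {
      r <- r + 1L
      x[r, ] <- cohort$eeg[i, ci, ei, ]
    }
    time_ms <- cohort$time_eeg
  } else {
    labels <- expand.grid(condition = conds, subject = subj$subject[ids],
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    labels$electrode <- NA_character_
    x <- matrix(NA_real_, nrow(labels), length(cohort$time_pdr))
    r <- 0L
    for (i in ids) for (ci in seq_along(conds)) {
      r <- r + 1L
      x[r, ] <- cohort$pupil[i, ci, ]
    }
    time_ms <- cohort$time_pdr
  }
  if (anyNA(x)) stopf("observation matrix contains missing values")
  labels$group <- subj$group[match(labels$subject, subj$subject)]
  sds <- apply(x, 2, stats::sd)
  if (nrow(x) < 2 || all(sds == 0))
    stopf("degenerate matrix: need >= 2 observations with variance")
  structure(list(X = x, labels = labels, time_ms = time_ms,
                 mu = colMeans(x), sd = sds,
                 fs = cohort$fs %||% NULL),
            class = "observation_matrix")
}

#' Horn's parallel analysis for component retention
#'
#' Compares the eigenvalues of the observed column covariance with those of
#' surrogate matrices of identical shape filled with independent Gaussian
#' noise matched to the observed column variances. The number of retained
#' components is the count of observed eigenvalues exceeding the surrogate
#' criterion (mean rule by default).
#'
#' @param om an `observation_matrix` (or plain matrix).
#' @param n_surrogates number of surrogate matrices (>= 50).
#' @param quantile_rule `NULL` for the mean rule, or a probability (e.g.
#'   0.95) for a quantile rule.
#' @param seed integer seed.
#' @return Integer `K`, with attributes `observed` and `criterion`
#'   (eigenvalue profiles).
#' @export
horns_parallel_test <- function(om, n_surrogates = 100,
                                quantile_rule = NULL, seed = 1L) {
  x <- if (inherits(om, "observation_matrix")) om$X else om
  if (n_surrogates < 50) stopf("n_surrogates must be >= 50")
  n <- nrow(x); p <- ncol(x)
  obs <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  sds <- apply(x, 2, stats::sd)
  sur <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      m <- matrix(rnorm(n * p), n, p) * rep(sds, each = n)
      eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(min(n, p) * 0 + p))
  })
  crit <- if (is.null(quantile_rule)) rowMeans(sur)
          else apply(sur, 1, stats::quantile, probs = quantile_rule)
  k <- 0L
  for (i in seq_along(obs)) {
    if (obs[i] > crit[i]) k <- k + 1L else break
  }
  structure(max(k, 0L), observed = obs, criterion = crit)
}

# Geomin complexity criterion and its gradient at a loading matrix.
geomin_vgQ <- function(L, epsilon) {
  k <- ncol(L)
  L2 <- L^2 + epsilon
  pro <- exp(rowMeans(log(L2)))
  list(f = sum(pro), Gq = (2 / k) * (L / L2) * pro)
}

#' Oblique Geomin rotation by gradient projection
#'
#' Minimizes the geomin criterion `sum_t (prod_k (lambda_tk^2 + eps))^(1/K)`
#' over oblique rotations using the gradient-projection algorithm, with
#' random orthogonal restarts; the best solution over starts is returned.
#' For `K = 1` the input is returned unchanged.
#'
#' @param loadings unrotated loadings (time x K).
#' @param epsilon geomin constant (the analysis default is 0.5).
#' @param n_starts random restarts in addition to the identity start and
#'   any `T_init` supplied.
#' @param T_init optional warm-start rotation matrix (K x K, unit-length
#'   columns), e.g. from a previous fit.
#' @param max_iter,tol iteration cap and relative-criterion convergence
#'   tolerance per start.
#' @param seed integer seed for the random starts.
#' @return List: `loadings` (rotated), `Phi` (factor correlations `t(T) T`),
#'   `Tmat`, `criterion`, `converged`.
#' @export
geomin_rotate <- function(loadings, epsilon = 0.5, n_starts = 30,
                          T_init = NULL, max_iter = 5000, tol = 1e-8,
                          seed = 1L) {
  k <- ncol(loadings)
  if (k < 2) {
    return(list(loadings = loadings, Phi = diag(1), Tmat = diag(1),
                criterion = geomin_vgQ(loadings, epsilon)$f,
                converged = TRUE))
  }
  # with a warm start and no random restarts the descent stays on the
  # warm start's branch (continuity across e.g. jackknife refits)
  starts <- if (is.null(T_init)) list(diag(k))
            else if (n_starts == 0) list(T_init)
            else list(diag(k), T_init)
  starts <- c(starts, with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      q <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
      q %*% diag(1 / sqrt(colSums(q^2)), k)
    })
  }))
  best <- NULL
  any_converged <- FALSE
  for (Tmat in starts) {
    res <- gp_oblique(loadings, Tmat, epsilon, max_iter, tol)
    any_converged <- any_converged || res$converged
    if (is.null(best) || res$criterion < best$criterion) best <- res
  }
  if (!any_converged && !best$converged)
    stopf("geomin rotation did not converge in any start (best criterion %g)",
          best$criterion)
  best
}

# One gradient-projection descent for oblique rotation (geomin criterion).
gp_oblique <- function(A, Tmat, epsilon, max_iter, tol) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- geomin_vgQ(L, epsilon)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < 1e-10) { converged <- TRUE; break }
    al <- 2 * al
    f_new <- f
    for (ls in 0:20) {
      X <- Tmat - al * Gp
      X <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Ti_new <- tryCatch(solve(X), error = function(e) NULL)
      if (!is.null(Ti_new)) {
        L_new <- A %*% t(Ti_new)
        vg_new <- geomin_vgQ(L_new, epsilon)
        if (vg_new$f < f - 0.5 * s^2 * al) { f_new <- vg_new$f; break }
      }
      al <- al / 2
    }
    if (is.null(Ti_new) || f_new >= f) { converged <- TRUE; break }
    rel <- (f - f_new) / max(abs(f), .Machine$double.eps)
    Tmat <- X; Ti <- Ti_new; L <- L_new; vg <- vg_new
    G <- -t(t(L) %*% vg$Gq %*% Ti)
    f <- f_new
    if (rel < tol) { converged <- TRUE; break }
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, Tmat = Tmat,
       criterion = f, converged = converged)
}

#' Covariance-based temporal PCA with Geomin rotation
#'
#' Eigendecomposition of the column (time point) covariance matrix, no
#' weighting; the top-K covariance-metric loadings are obliquely rotated by
#' geomin. Scores are computed so that the reconstruction identity holds:
#' with all components retained, `scores %*% t(loadings_scaled) + mu`
#' reproduces the observation matrix. `loadings_scaled` are in physical
#' units (uV or mm): the contribution of component k to observation o is
#' `scores[o, k] * loadings_scaled[, k]`. `loadings` are the SD-scaled
#' (correlation-metric) loadings `loadings_scaled / sd`.
#'
#' Component signs are fixed so the largest-magnitude point of each scaled
#' loading is positive (ties toward the earlier peak); components are
#' ordered by explained variance.
#'
#' @param om an `observation_matrix`.
#' @param K number of components (e.g. from [horns_parallel_test()]).
#' @param epsilon geomin constant.
#' @param n_starts,T_init,seed rotation controls, see [geomin_rotate()].
#' @return A `tpca` object: `loadings_scaled` (time x K), `loadings`,
#'   `scores` (obs x K), `Phi`, `explained_variance` (unrotated eigenvalue
#'   fractions, length K), `variance_rotated` (sum of squared scaled
#'   loadings per rotated component), `criterion`, `mu`, `sd`, `labels`,
#'   `time_ms`, `K`.
#' @export
fit_temporal_pca <- function(om, K, epsilon = 0.5, n_starts = 30,
                             T_init = NULL, seed = 1L) {
  x <- om$X
  cv <- stats::cov(x)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  rank <- sum(pos)
  if (K < 1 || K > rank)
    stopf("K = %d outside 1..rank(X) = %d", K, rank)
  d <- eg$values[seq_len(K)]
  v <- eg$vectors[, seq_len(K), drop = FALSE]
  A <- v %*% diag(sqrt(d), K)                      # covariance-metric
  xc <- sweep(x, 2, om$mu)
  S <- xc %*% v %*% diag(1 / sqrt(d), K)           # unit-variance scores
  # rotation criterion evaluated on SD-standardized (correlation-metric)
  # loadings; the same oblique transform is applied to the covariance-metric
  # loadings, so the reconstruction identity is untouched
  sd_safe <- ifelse(om$sd > 0, om$sd, 1)
  rot <- geomin_rotate(A / sd_safe, epsilon = epsilon, n_starts = n_starts,
                       T_init = T_init, seed = seed)
  Tmat <- rot$Tmat
  L <- A %*% t(solve(Tmat))
  S <- S %*% Tmat
  Phi <- rot$Phi
  # sign convention: largest |loading| point positive, ties -> earlier
  for (kk in seq_len(K)) {
    pk <- which(abs(L[, kk]) == max(abs(L[, kk])))[1]
    if (L[pk, kk] < 0) {
      L[, kk] <- -L[, kk]
      S[, kk] <- -S[, kk]
      Tmat[, kk] <- -Tmat[, kk]
      Phi[kk, -kk] <- -Phi[kk, -kk]
      Phi[-kk, kk] <- -Phi[-kk, kk]
    }
  }
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  S <- S[, ord, drop = FALSE]
  Tmat <- Tmat[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  total_var <- sum(eg$values[pos])
  structure(list(
    loadings_scaled = L,
    loadings = L / sd_safe,
    scores = S, Phi = Phi,
    explained_variance = d / total_var,
    variance_rotated = colSums(L^2),
    criterion = rot$criterion,
    mu = om$mu, sd = om$sd, labels = om$labels, time_ms = om$time_ms,
    K = K, epsilon = epsilon, rank = rank, Tmat = Tmat),
    class = "tpca")
}

#' Reconstruct a component's time course in physical units
#'
#' The contribution of component k to an observation is the scaled loading
#' multiplied by the observation's score; subsets of observations are
#' averaged.
#'
#' @param fit a `tpca`.
#' @param k component index.
#' @param subject,condition,electrode optional label filters.
#' @param average average over the selected observations (otherwise a
#'   matrix, one row per observation).
#' @return Numeric time course (or matrix) in uV/mm.
#' @export
reconstruct_component_timecourse <- function(fit, k, subject = NULL,
                                             condition = NULL,
                                             electrode = NULL,
                                             average = TRUE) {
  if (k < 1 || k > fit$K) stopf("component %d not in 1..%d", k, fit$K)
  sel <- select_observations(fit$labels, subject, condition, electrode)
  tc <- outer(fit$scores[sel, k], fit$loadings_scaled[, k])
  if (average) colMeans(tc) else tc
}

select_observations <- function(labels, subject = NULL, condition = NULL,
                                electrode = NULL) {
  sel <- rep(TRUE, nrow(labels))
  if (!is.null(subject)) {
    if (!all(subject %in% labels$subject)) stopf("unknown subject label")
    sel <- sel & labels$subject %in% subject
  }
  if (!is.null(condition)) {
    if (!all(condition %in% labels$condition)) stopf("unknown condition label")
    sel <- sel & labels$condition %in% condition
  }
  if (!is.null(electrode)) {
    if (!all(electrode %in% labels$electrode)) stopf("unknown electrode label")
    sel <- sel & labels$electrode %in% electrode
  }
  if (!any(sel)) stopf("no observations match the requested labels")
  which(sel)
}
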