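#' Symmetric FastICA decomposition
#'
#' Fixed-point ICA with the logcosh contrast and symmetric decorrelation,
#' estimated on row-centered, eigenvalue-whitened data. Used as the default
#' backend of the two-pass ocular cleaning; any function with the same
#' return contract can be plugged in instead.
#'
#' @param x channels x samples matrix.
#' @param n_comp number of components (default: number of channels).
#' @param seed integer seed for the random orthogonal initialization.
#' @param max_iter,tol fixed-point iteration controls.
#' @return List: `demixing` (components x channels, applied to row-centered
#'   data), `mixing` (channels x components, its pseudo-inverse),
#'   `activations` (components x samples), `row_means`, `converged`,
#'   `iterations`.
#' @export
fastica_decompose <- function(x, n_comp = nrow(x), seed = 1L,
                              max_iter = 500L, tol = 1e-6) {
  stopifnot(is.matrix(x), n_comp >= 1, n_comp <= nrow(x))
  mu <- rowMeans(x)
  xc <- x - mu
  n <- ncol(xc)
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  if (any(eg$values[keep] <= .Machine$double.eps * eg$values[1] * nrow(x)))
    stopf("data are rank-deficient; reduce n_comp")
  K <- diag(1 / sqrt(eg$values[keep]), n_comp) %*% t(eg$vectors[, keep])
  z <- K %*% xc

  sym_decor <- function(w) {
    s <- eigen(tcrossprod(w), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), n_comp) %*% t(s$vectors) %*% w
  }
  w <- with_seed(seed,
    matrix(rnorm(n_comp * n_comp), n_comp, n_comp))
  w <- sym_decor(w)
  # convergence: either the classic fixed-point alignment criterion, or a
  # plateau of the negentropy objective. Directions with non-Gaussian
  # sources converge quickly; a residual near-Gaussian subspace has no
  # fixed point (it is rotation-invariant), so the objective plateau is the
  # meaningful stopping rule there.
  e_g_gauss <- 0.3745672  # E[log cosh nu], nu ~ N(0,1)
  objective <- function(g_log) sum((rowMeans(g_log) - e_g_gauss)^2)
  converged <- FALSE
  it <- 0L
  obj_old <- -Inf
  plateau <- 0L
  while (it < max_iter) {
    it <- it + 1L
    wz <- w %*% z
    g <- tanh(wz)
    gp_mean <- rowMeans(1 - g^2)
    w1 <- sym_decor(g %*% t(z) / n - gp_mean * w)
    delta <- max(abs(abs(rowSums(w1 * w)) - 1))
    obj <- objective(log(cosh(wz)))
    plateau <- if (abs(obj - obj_old) < 1e-3 * max(obj, 1e-12))
      plateau + 1L else 0L
    obj_old <- obj
    w <- w1
    if (delta < tol || plateau >= 5L) { converged <- TRUE; break }
  }
  if (!converged)
    stopf("FastICA did not converge in %d iterations", max_iter)
  demix <- w %*% K
  mixing <- t(demix) %*% solve(tcrossprod(demix))
  list(demixing = demix, mixing = mixing, activations = demix %*% xc,
       row_means = mu, converged = converged, iterations = it)
}

#' Two-pass ICA ocular cleaning
#'
#' ICA is estimated on an aggressively highpass-filtered (1 Hz) copy of the
#' recording, where slow drifts do not dominate the decomposition; the
#' resulting demixing matrix is applied to the analysis copy (0.1-40 Hz).
#' Components whose activation correlates with any EOG channel beyond the
#' threshold (absolute Pearson correlation) are flagged as ocular, their
#' activations zeroed, and the data remixed.
#'
#' @param eeg_1hz,eeg_0p1hz channels x samples matrices with identical
#'   channel order and length: the ICA training copy and the analysis copy.
#' @param eog eog-channels x samples matrix (same sample grid).
#' @param threshold absolute correlation above which a component is ocular.
#' @param backend ICA function with the [fastica_decompose()] contract.
#' @param ... passed to the backend (e.g. `seed`).
#' @return List: `cleaned` (channels x samples), `flagged` (component
#'   indices), `fraction_removed`, `correlations` (components x EOG),
#'   `decomposition`.
#' @export
ica_ocular_clean <- function(eeg_1hz, eeg_0p1hz, eog, threshold = 0.8,
                             backend = fastica_decompose, ...) {
  stopifnot(identical(dim(eeg_1hz), dim(eeg_0p1hz)))
  if (ncol(eog) != ncol(eeg_1hz))
    stopf("EOG and EEG must share the sample grid")
  dec <- backend(eeg_1hz, ...)
  cors <- stats::cor(t(dec$activations), t(eog))
  flagged <- which(apply(abs(cors), 1, max) > threshold)
  if (length(flagged) == 0) {
    warning("no ICA component exceeded the EOG correlation threshold; ",
            "signal passed through unchanged")
    return(list(cleaned = eeg_0p1hz, flagged = integer(0),
                fraction_removed = 0, correlations = cors,
                decomposition = dec))
  }
  mu <- rowMeans(eeg_0p1hz)
  s0 <- dec$demixing %*% (eeg_0p1hz - mu)
  s0[flagged, ] <- 0
  cleaned <- dec$mixing %*% s0 + mu
  dimnames(cleaned) <- dimnames(eeg_0p1hz)
  list(cleaned = cleaned, flagged = flagged,
       fraction_removed = length(flagged) / nrow(dec$demixing),
       correlations = cors, decomposition = dec)
}
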