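#' Component templates of the oddball analysis
#'
#' Expected peak windows, polarities and analysis electrodes for the
#' components of interest: P2 and early P3a at Cz, late P3a at Fz, LDN at
#' F4; the biphasic pupil dilation response has an early (~640 ms) and a
#' late (~1520 ms) component, analyzed without an electrode dimension.
#'
#' @param modality `"eeg"` or `"pupil"`.
#' @return Data frame with `name`, `window_lo`, `window_hi` (ms),
#'   `polarity` (+1/-1), `electrode`.
#' @export
component_templates <- function(modality = c("eeg", "pupil")) {
  modality <- match.arg(modality)
  if (modality == "eeg") {
    data.frame(
      name = c("P2", "eP3a", "lP3a", "LDN"),
      window_lo = c(120, 180, 260, 550),
      window_hi = c(230, 340, 440, 790),
      polarity = c(1, 1, 1, -1),
      electrode = c("Cz", "Cz", "Fz", "F4"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      name = c("PDR_early", "PDR_late"),
      window_lo = c(250, 1050),
      window_hi = c(1050, 1900),
      polarity = c(1, 1),
      electrode = NA_character_,
      stringsAsFactors = FALSE
    )
  }
}

# Peak time (ms) of each scaled loading; ties toward the earlier sample.
loading_peak_times <- function(fit) {
  vapply(seq_len(fit$K), function(k) {
    l <- abs(fit$loadings_scaled[, k])
    fit$time_ms[which(l == max(l))[1]]
  }, numeric(1))
}

#' Match component templates to fitted components
#'
#' A template matches the component whose scaled-loading peak lies in the
#' template window, whose reconstructed contribution at the template
#' electrode (novel observations) has the template polarity, and whose peak
#' magnitude there is maximal. Templates without a match are reported with
#' `NA`.
#'
#' @param fit a `tpca`.
#' @param templates data frame as from [component_templates()].
#' @param resolve_ambiguity if `FALSE` (default), two templates claiming the
#'   same component raise an ambiguity error listing the candidates; if
#'   `TRUE`, claims are resolved greedily by descending contribution
#'   magnitude and losing templates fall back to their next candidate.
#' @return Named integer vector (template name -> component index, `NA` if
#'   unmatched), with attribute `details` (per-template candidates).
#' @export
identify_components <- function(fit, templates, resolve_ambiguity = FALSE) {
  peaks <- loading_peak_times(fit)
  assignment <- setNames(rep(NA_integer_, nrow(templates)), templates$name)
  details <- list()
  cand_list <- list()
  for (ti in seq_len(nrow(templates))) {
    tpl <- templates[ti, ]
    rows <- if (!is.na(tpl$electrode) &&
                "electrode" %in% names(fit$labels) &&
                !all(is.na(fit$labels$electrode))) {
      sel <- fit$labels$electrode == tpl$electrode
      nov <- fit$labels$condition != "standard"
      if (any(sel & nov)) which(sel & nov) else which(sel)
    } else {
      nov <- fit$labels$condition != "standard"
      if (any(nov)) which(nov) else seq_len(nrow(fit$labels))
    }
    cand <- which(peaks >= tpl$window_lo & peaks <= tpl$window_hi)
    contrib <- numeric(0)
    if (length(cand) > 0) {
      contrib <- vapply(cand, function(k) {
        pk <- which.max(abs(fit$loadings_scaled[, k]))
        mean(fit$scores[rows, k]) * fit$loadings_scaled[pk, k]
      }, numeric(1))
      ok <- sign(contrib) == tpl$polarity
      cand <- cand[ok]; contrib <- contrib[ok]
      ord <- order(abs(contrib), decreasing = TRUE)
      cand <- cand[ord]; contrib <- contrib[ord]
      if (length(cand) > 0) assignment[ti] <- cand[1]
    }
    cand_list[[tpl$name]] <- list(cand = cand, contrib = contrib)
    details[[tpl$name]] <- cand
  }
  dup <- assignment[!is.na(assignment)]
  if (anyDuplicated(dup)) {
    if (!resolve_ambiguity) {
      amb <- names(dup)[dup %in% dup[duplicated(dup)]]
      stopf("templates %s match the same component (candidates: %s)",
            paste(amb, collapse = ", "),
            paste(unique(dup[duplicated(dup)]), collapse = ", "))
    }
    # greedy exclusive assignment by descending contribution magnitude
    assignment[] <- NA_integer_
    claims <- do.call(rbind, lapply(names(cand_list), function(nm) {
      cl <- cand_list[[nm]]
      if (length(cl$cand) == 0) return(NULL)
      data.frame(template = nm, component = cl$cand,
                 magnitude = abs(cl$contrib), stringsAsFactors = FALSE)
    }))
    claims <- claims[order(-claims$magnitude), ]
    for (r in seq_len(nrow(claims))) {
      nm <- claims$template[r]; k <- claims$component[r]
      if (is.na(assignment[nm]) && !k %in% assignment)
        assignment[nm] <- k
    }
  }
  attr(assignment, "details") <- details
  assignment
}

#' Mean amplitude around a peak
#'
#' Arithmetic mean of a time course over the window `peak +/- halfwidth`
#' (inclusive at both ends).
#'
#' @param timecourse numeric values on the `time_ms` grid.
#' @param time_ms time axis, ms.
#' @param peak_ms window centre, ms.
#' @param halfwidth_ms half window width, ms.
#' @return Mean amplitude in the time course's units.
#' @export
mean_amplitude <- function(timecourse, time_ms, peak_ms,
                           halfwidth_ms = 20) {
  lo <- peak_ms - halfwidth_ms
  hi <- peak_ms + halfwidth_ms
  if (lo < min(time_ms) || hi > max(time_ms))
    stopf("amplitude window [%g, %g] ms clipped by the epoch", lo, hi)
  idx <- which(time_ms >= lo & time_ms <= hi)
  mean(timecourse[idx])
}

#' Novel-minus-standard difference amplitude
#'
#' @param novel_amp,standard_amp mean amplitudes of the same subject,
#'   component and electrode.
#' @return `novel_amp - standard_amp`.
#' @export
difference_amplitude <- function(novel_amp, standard_amp) {
  novel_amp - standard_amp
}

#' Per-subject component amplitude table
#'
#' For one identified component: reconstructs each subject's condition time
#' course at the template electrode, measures the mean amplitude around the
#' component's loading peak (+/- 20 ms), and forms novel-minus-standard
#' differences per emotion condition.
#'
#' @param fit a `tpca`.
#' @param k component index.
#' @param electrode analysis electrode (`NA` for pupil fits).
#' @param halfwidth_ms amplitude window half width.
#' @return Data frame: `subject`, `group`, `condition`, `amplitude`, and
#'   (for novel conditions) `difference`.
#' @export
component_amplitudes <- function(fit, k, electrode = NA,
                                 halfwidth_ms = 20) {
  peak_ms <- loading_peak_times(fit)[k]
  lab <- fit$labels
  subjects <- unique(lab$subject)
  rows <- lapply(subjects, function(s) {
    conds <- unique(lab$condition)
    amp <- vapply(conds, function(cn) {
      tc <- reconstruct_component_timecourse(
        fit, k, subject = s, condition = cn,
        electrode = if (is.na(electrode)) NULL else electrode)
      mean_amplitude(tc, fit$time_ms, peak_ms, halfwidth_ms)
    }, numeric(1))
    data.frame(subject = s,
               group = lab$group[match(s, lab$subject)],
               condition = conds, amplitude = amp,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  std <- out$amplitude[out$condition == "standard"]
  names(std) <- out$subject[out$condition == "standard"]
  out$difference <- ifelse(
    out$condition == "standard", NA_real_,
    difference_amplitude(out$amplitude,
                         std[as.character(out$subject)]))
  out
}

# Earliest point within the window at which the (sign-aligned) loading
# reaches the criterion fraction of its in-window peak, scanning forward;
# the crossing is linearly interpolated between the bracketing samples so
# that jackknife pseudo-values are not dominated by grid quantization.
criterion_latency <- function(loading, time_ms, window, criterion = 0.8) {
  idx <- which(time_ms >= window[1] & time_ms <= window[2])
  lv <- loading[idx]
  tv <- time_ms[idx]
  thr <- criterion * max(lv)
  i <- which(lv >= thr)[1]
  if (i == 1) return(tv[1])
  tv[i - 1] + (thr - lv[i - 1]) / (lv[i] - lv[i - 1]) * (tv[i] - tv[i - 1])
}

#' Jackknife 80%-relative component latencies with individual retrieval
#'
#' The full-sample latency is the earliest time inside the template window
#' at which the component's scaled loading reaches the criterion fraction of
#' its peak. The PCA is then refitted once per leave-one-subject-out
#' subsample (same K, rotation warm-started from the full-sample solution);
#' in each refit the component is re-identified as the one whose scaled
#' loading correlates maximally (in absolute value) with the full-sample
#' component, sign-aligned. Individual latencies are retrieved as jackknife
#' pseudo-values `o_i = n * theta_hat - (n - 1) * theta_hat_(-i)`, restoring
#' the between-subject variance that leave-one-out estimates suppress.
#'
#' @param om an `observation_matrix` (one group).
#' @param K number of components.
#' @param template one row of [component_templates()].
#' @param criterion relative amplitude criterion (0.8).
#' @param epsilon geomin constant.
#' @param n_starts_full,n_starts_sub rotation restarts for the full fit and
#'   the warm-started subsample refits (0: follow the full-sample rotation's
#'   branch only, keeping leave-one-out solutions continuous).
#' @param seed integer seed.
#' @return A `latency_estimates` list: `theta_full` (ms), `loo` (leave-one-
#'   out latencies, named by subject), `retrieved` (pseudo-values),
#'   `component`, `n`, `criterion`.
#' @export
jackknife_latencies <- function(om, K, template, criterion = 0.8,
                                epsilon = 0.5, n_starts_full = 30,
                                n_starts_sub = 0, seed = 1L) {
  subjects <- unique(om$labels$subject)
  n <- length(subjects)
  if (n < 3) stopf("jackknife needs >= 3 subjects")
  window <- c(template$window_lo, template$window_hi)
  full <- fit_temporal_pca(om, K, epsilon = epsilon,
                           n_starts = n_starts_full, seed = seed)
  k_full <- identify_components(full, template)[template$name]
  if (is.na(k_full))
    stopf("template '%s' unmatched in the full-sample fit", template$name)
  ref <- full$loadings_scaled[, k_full]
  theta <- criterion_latency(ref, full$time_ms, window, criterion)

  # leave-one-out refits via covariance downdating: remove each subject's
  # rows from the precomputed cross-products instead of re-forming X'X
  x <- om$X
  m_all <- nrow(x)
  cs_all <- colSums(x)
  cp_all <- crossprod(x)
  sd_safe <- ifelse(om$sd > 0, om$sd, 1)
  a_ref_std <- (full$loadings_scaled %*% t(full$Tmat)) / sd_safe
  loo <- setNames(numeric(n), subjects)
  for (i in seq_len(n)) {
    drop_rows <- which(om$labels$subject == subjects[i])
    xi <- x[drop_rows, , drop = FALSE]
    m <- m_all - length(drop_rows)
    cs <- cs_all - colSums(xi)
    cp <- cp_all - crossprod(xi)
    cv <- (cp - tcrossprod(cs) / m) / (m - 1)
    l_i <- loadings_from_cov(cv, K, epsilon, n_starts_sub, full$Tmat,
                             child_seed(seed, i), A_ref = a_ref_std)
    if (is.null(l_i))
      stopf("subsample fit failed leaving out subject %s", subjects[i])
    cors <- stats::cor(l_i, ref)
    k_i <- which.max(abs(cors))
    if (abs(cors[k_i]) < 0.5)
      stopf("component unmatched in subsample leaving out subject %s",
            subjects[i])
    loo[i] <- criterion_latency(l_i[, k_i] * sign(cors[k_i]),
                                om$time_ms, window, criterion)
  }
  retrieved <- n * theta - (n - 1) * loo
  structure(list(theta_full = theta, loo = loo, retrieved = retrieved,
                 component = unname(k_full), n = n, criterion = criterion,
                 template = template$name),
            class = "latency_estimates")
}

# Scaled loadings of a covariance-only temporal PCA refit (no scores).
# The unrotated basis is first Procrustes-aligned to the reference basis:
# eigenvectors within near-degenerate eigenvalue clusters are only defined
# up to rotation, so without alignment a warm-started rotation would start
# from an arbitrarily mixed basis and jackknife refits would jump branches.
loadings_from_cov <- function(cv, K, epsilon, n_starts, T_init, seed,
                              A_ref = NULL) {
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[K] <= 0) return(NULL)
  A <- eg$vectors[, seq_len(K), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(K)]), K)
  sds <- sqrt(pmax(diag(cv), 0))
  sd_safe <- ifelse(sds > 0, sds, 1)
  if (!is.null(A_ref)) {
    sv <- svd(crossprod(A / sd_safe, A_ref))
    A <- A %*% (sv$u %*% t(sv$v))
  }
  rot <- geomin_rotate(A / sd_safe, epsilon = epsilon,
                       n_starts = n_starts, T_init = T_init, seed = seed)
  A %*% t(solve(rot$Tmat))
}
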