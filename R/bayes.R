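#' JZS Bayes factor for a t-test
#'
#' Default-prior Bayes factor with a zero-centered Cauchy prior of scale `r`
#' on the standardized effect size, computed by one-dimensional numerical
#' integration over the g-prior mixing variable (deterministic).
#'
#' @param x first sample, or the paired differences / single sample when
#'   `y` is `NULL`.
#' @param y optional second sample (independent two-sample test).
#' @param r Cauchy prior scale on the standardized effect.
#' @return `BF10`, evidence for a nonzero effect relative to the point null.
#' @export
jzs_ttest_bf <- function(x, y = NULL, r = sqrt(2) / 2) {
  if (is.null(y)) {
    if (length(x) < 2) stopf("need >= 2 values")
    if (stats::var(x) == 0) stopf("zero variance")
    n_eff <- length(x)
    nu <- length(x) - 1
    t <- mean(x) / sqrt(stats::var(x) / length(x))
  } else {
    if (length(x) < 2 || length(y) < 2) stopf("need >= 2 values per sample")
    if (stats::var(x) + stats::var(y) == 0) stopf("zero variance in both
 samples")
    n1 <- length(x); n2 <- length(y)
    n_eff <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / nu
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  jzs_bf_from_t(t, n_eff, nu, r)
}

#' @rdname jzs_ttest_bf
#' @param t observed t statistic.
#' @param n_eff effective sample size (`n` one-sample,
#'   `n1*n2/(n1+n2)` two-sample).
#' @param nu degrees of freedom.
#' @export
jzs_bf_from_t <- function(t, n_eff, nu, r = sqrt(2) / 2) {
  # marginal under H1: integral over g ~ InvGamma(1/2, r^2/2) of
  # (1+Ng)^(-1/2) * (1 + t^2/((1+Ng)nu))^(-(nu+1)/2); H0 is g = 0.
  log_h0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(-0.5 * log1p(n_eff * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + n_eff * g) * nu)) +
          stats::dgamma(1 / g, shape = 0.5, rate = r^2 / 2, log = TRUE) -
          2 * log(g) - log_h0)
  }
  # split the integral at the prior median to help the quadrature
  med <- r^2 / stats::qgamma(0.5, shape = 0.5, rate = r^2 / 2)
  i1 <- stats::integrate(integrand, 0, med, rel.tol = 1e-10)$value
  i2 <- stats::integrate(integrand, med, Inf, rel.tol = 1e-10)$value
  i1 + i2
}

#' Verbal evidence categories for Bayes factors
#'
#' Moderate evidence for an effect when BF10 exceeds 3 and strong when it
#' exceeds 10; mirrored against the effect below 1/3 and 1/10; between 1/3
#' and 3 the evidence is weak/anecdotal.
#'
#' @param bf a positive Bayes factor (BF10 or BF_Incl).
#' @return One of `"strong evidence for"`, `"moderate evidence for"`,
#'   `"weak/anecdotal evidence"`, `"moderate evidence against"`,
#'   `"strong evidence against"`.
#' @export
classify_evidence <- function(bf) {
  if (!is.finite(bf) || bf <= 0) stopf("BF must be positive")
  if (bf > 10) "strong evidence for"
  else if (bf > 3) "moderate evidence for"
  else if (bf >= 0.33) "weak/anecdotal evidence"
  else if (bf >= 0.1) "moderate evidence against"
  else "strong evidence against"
}

# Orthonormal sum-to-zero contrast columns for a factor with a levels:
# the eigenvectors of the centering matrix I - J/a with unit eigenvalue.
orthonormal_contrasts <- function(a) {
  c_mat <- diag(a) - 1 / a
  eg <- eigen(c_mat, symmetric = TRUE)
  eg$vectors[, seq_len(a - 1), drop = FALSE]
}

# Build the coded design columns per effect term for a balanced long table.
build_effect_columns <- function(d, between, within, subject) {
  factors <- c(between, within)
  codes <- lapply(factors, function(f) {
    lev <- levels(d[[f]])
    q <- orthonormal_contrasts(length(lev))
    q[as.integer(d[[f]]), , drop = FALSE]
  })
  names(codes) <- factors
  effects <- list()
  for (ord in seq_along(factors)) {
    for (comb in utils::combn(factors, ord, simplify = FALSE)) {
      x <- codes[[comb[1]]]
      for (f in comb[-1]) {
        x2 <- codes[[f]]
        x <- do.call(cbind, lapply(seq_len(ncol(x2)), function(j)
          x * x2[, j]))
      }
      effects[[paste(comb, collapse = ":")]] <- x
    }
  }
  qs <- orthonormal_contrasts(nlevels(d[[subject]]))
  effects[[".subject"]] <- qs[as.integer(d[[subject]]), , drop = FALSE]
  effects
}

# All submodels of the fixed effects respecting marginality (an interaction
# requires all its margins); the subject term is always included.
enumerate_models <- function(effect_names) {
  parts <- strsplit(effect_names, ":", fixed = TRUE)
  n <- length(effect_names)
  models <- list()
  for (bits in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(bits, 2^(seq_len(n) - 1)))
    ok <- TRUE
    for (i in which(sel)) {
      if (length(parts[[i]]) > 1) {
        for (sub in utils::combn(parts[[i]], length(parts[[i]]) - 1,
                                 simplify = FALSE)) {
          j <- match(paste(sort(sub), collapse = ":"),
                     vapply(parts, function(p)
                       paste(sort(p), collapse = ":"), character(1)))
          if (is.na(j) || !sel[j]) { ok <- FALSE; break }
        }
      }
      if (!ok) break
    }
    if (ok) models[[length(models) + 1]] <- effect_names[sel]
  }
  models
}

#' Default-prior Bayesian mixed ANOVA by model comparison
#'
#' Enumerates all submodels of the fixed effects that respect marginality,
#' each including the participant random effect, and computes each model's
#' Bayes factor against the participant-only null under the default g-prior
#' linear-model formulation: effects are orthonormally contrast-coded, one
#' common g per term with `g ~ InvGamma(1/2, r^2/2)` (scale `r_fixed` for
#' fixed-effect terms, `r_random` for the participant term), the conditional
#' marginal given g in closed form, and g integrated by seeded Monte Carlo
#' sampling from the prior. The Monte Carlo standard error of each log BF10
#' is estimated by batching.
#'
#' @param table long-format data frame (balanced).
#' @param dv,subject,between,within column names as in [mixed_anova()].
#' @param r_fixed,r_random prior scales (defaults 0.5 and 1, the "medium"
#'   fixed and "nuisance" random defaults).
#' @param iterations Monte Carlo draws (default 50000).
#' @param seed integer seed; identical seeds give identical BFs.
#' @return A `bayes_result` list: `models` (data frame with `model`, `bf10`,
#'   `log_bf10`, `mc_se_log`), `effects` (the fixed-effect term names),
#'   `iterations`, `r_fixed`, `r_random`, `seed`.
#' @export
bayes_anova <- function(table, dv = "value", subject = "subject",
                        between = "group", within = "emotion",
                        r_fixed = 0.5, r_random = 1,
                        iterations = 50000, seed = 1L) {
  if (r_fixed <= 0 || r_random <= 0) stopf("prior scales must be positive")
  d <- data.frame(y = table[[dv]],
                  subject = factor(table[[subject]]))
  for (f in c(between, within)) d[[f]] <- factor(table[[f]])
  dd <- d; names(dd)[1] <- "y"
  dd$g <- d[[between]]
  for (i in seq_along(within)) dd[[paste0("w", i)]] <- d[[within[i]]]
  check_balanced(dd, length(within))
  # with a single observation per subject the participant effect is
  # confounded with the residual; the null is then the intercept-only model
  # and the design reduces to a fixed-effects (e.g. two-sample JZS) setup
  include_subject <- max(table(d$subject)) > 1

  cols <- build_effect_columns(d, between, within, "subject")
  if (!include_subject) cols[[".subject"]] <- NULL
  effect_names <- setdiff(names(cols), ".subject")
  y <- d$y - mean(d$y)
  x_all <- do.call(cbind, cols)
  term_of_col <- rep(names(cols), vapply(cols, ncol, integer(1)))
  xtx <- crossprod(x_all)
  xty <- crossprod(x_all, y)
  yty <- sum(y^2)
  n <- length(y)

  models <- enumerate_models(effect_names)
  r_of_term <- setNames(c(rep(r_fixed, length(effect_names)), r_random),
                        c(effect_names, ".subject"))

  log_marg <- function(terms, seed_m) {
    keep <- term_of_col %in% terms
    m_xtx <- xtx[keep, keep, drop = FALSE]
    m_xty <- xty[keep, , drop = FALSE]
    m_terms <- term_of_col[keep]
    u_terms <- unique(m_terms)
    term_idx <- match(m_terms, u_terms)
    rs <- r_of_term[u_terms]
    with_seed(seed_m, {
      lf <- numeric(iterations)
      for (it in seq_len(iterations)) {
        g <- rs^2 / stats::rchisq(length(rs), df = 1)
        sg <- sqrt(g)[term_idx]
        m <- m_xtx * tcrossprod(sg)
        diag(m) <- diag(m) + 1
        ch <- chol(m)
        b <- forwardsolve(t(ch), sg * m_xty)
        rss <- yty - sum(b^2)
        lf[it] <- -sum(log(diag(ch))) -
          (n - 1) / 2 * (log(rss) - log(yty))
      }
      lf
    })
  }

  null_lf <- if (include_subject) log_marg(".subject", child_seed(seed, 0))
             else numeric(iterations)
  res <- lapply(seq_along(models), function(mi) {
    terms <- c(models[[mi]], if (include_subject) ".subject")
    lf <- if (length(models[[mi]]) == 0) null_lf
          else log_marg(terms, child_seed(seed, mi))
    lb <- logmeanexp(lf) - logmeanexp(null_lf)
    nb <- 50
    batches <- split(seq_len(iterations),
                     rep(seq_len(nb), length.out = iterations))
    bm <- vapply(batches, function(ix)
      logmeanexp(lf[ix]) - logmeanexp(null_lf[ix]), numeric(1))
    data.frame(model = paste(models[[mi]], collapse = " + "),
               log_bf10 = lb, bf10 = exp(lb),
               mc_se_log = stats::sd(bm) / sqrt(nb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$model[out$model == ""] <- if (include_subject) "(participant only)"
                                else "(intercept only)"
  structure(list(models = out, effects = effect_names,
                 model_terms = models, iterations = iterations,
                 r_fixed = r_fixed, r_random = r_random, seed = seed),
            class = "bayes_result")
}

#' Matched-models inclusion Bayes factor
#'
#' Evidence for one effect from the matched model pairs: models that contain
#' the effect but no higher-order interaction involving it, against the same
#' models with the effect removed. With equal prior model odds this is the
#' ratio of summed model Bayes factors over the two sets.
#'
#' @param bayes_result a [bayes_anova()] result.
#' @param effect effect name (e.g. `"group:emotion"`).
#' @return `BF_Incl` for the effect.
#' @export
inclusion_bf <- function(bayes_result, effect) {
  terms <- bayes_result$model_terms
  if (!effect %in% bayes_result$effects)
    stopf("effect '%s' not in the model space", effect)
  facs <- strsplit(effect, ":", fixed = TRUE)[[1]]
  involves_higher <- function(m) {
    any(vapply(m, function(t) {
      tf <- strsplit(t, ":", fixed = TRUE)[[1]]
      length(tf) > length(facs) && all(facs %in% tf)
    }, logical(1)))
  }
  key <- function(m) paste(sort(m), collapse = "|")
  keys <- vapply(terms, key, character(1))
  bf_of <- function(m) bayes_result$models$bf10[match(key(m), keys)]
  num <- den <- 0
  found <- FALSE
  for (m in terms) {
    if (effect %in% m && !involves_higher(m)) {
      m0 <- setdiff(m, effect)
      if (is.na(bf_of(m0))) next  # reduced model invalid (marginality)
      found <- TRUE
      num <- num + bf_of(m)
      den <- den + bf_of(m0)
    }
  }
  if (!found) stopf("no matched model pair for effect '%s'", effect)
  num / den
}
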