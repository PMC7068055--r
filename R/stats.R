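#' Frequentist mixed (repeated-measures) ANOVA with eta-squared
#'
#' Classical sums-of-squares partitioning for a balanced design with one
#' between-subject factor and up to two within-subject factors, fitted with
#' `stats::aov` using an `Error(subject/...)` stratification: the between
#' effect is tested against subjects-within-group, each within effect and
#' its interactions with the between factor against the corresponding
#' subject-by-effect error term. Effect sizes are
#' `eta^2 = SS_effect / SS_total`.
#'
#' @param table long-format data frame.
#' @param dv,subject,between,within column names; `within` may name one or
#'   two factors.
#' @return An `anova_result` data frame: `effect`, `F`, `df1`, `df2`, `p`,
#'   `eta_sq`. Degenerate zero-variance data yield `F = 0`, `p = 1`,
#'   `eta_sq = 0`.
#' @export
mixed_anova <- function(table, dv = "value", subject = "subject",
                        between = "group", within = "emotion") {
  stopifnot(all(c(dv, subject, between, within) %in% names(table)))
  if (length(within) > 2) stopf("at most two within factors supported")
  d <- data.frame(
    y = table[[dv]],
    subject = factor(table[[subject]]),
    g = factor(table[[between]])
  )
  for (i in seq_along(within)) d[[paste0("w", i)]] <- factor(table[[within[i]]])
  check_balanced(d, length(within))

  wnames <- paste0("w", seq_along(within))
  rhs <- paste(c("g", wnames), collapse = " * ")
  err <- if (length(within) == 1) "Error(subject/w1)"
         else "Error(subject/(w1 * w2))"
  form <- stats::as.formula(paste("y ~", rhs, "+", err))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)

  rows <- list()
  ss_total <- 0
  for (stratum in sm) {
    tab <- stratum[[1]]
    ss_total <- ss_total + sum(tab[["Sum Sq"]])
    resid <- rownames(tab) == "Residuals"
    for (r in which(!resid)) {
      rows[[length(rows) + 1]] <- data.frame(
        effect = trimws(rownames(tab)[r]),
        ss = tab[["Sum Sq"]][r],
        F = tab[["F value"]][r],
        df1 = tab[["Df"]][r],
        df2 = tab[["Df"]][resid],
        p = tab[["Pr(>F)"]][r],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$F[!is.finite(out$F)] <- 0
  out$p[!is.finite(out$p)] <- 1
  out$eta_sq <- if (ss_total > 0) out$ss / ss_total else 0
  # map coded names back to user-facing factor names
  repl <- c(g = between, setNames(within, wnames))
  out$effect <- vapply(strsplit(out$effect, ":"), function(parts)
    paste(ifelse(parts %in% names(repl), repl[parts], parts),
          collapse = ":"), character(1))
  out$ss <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

check_balanced <- function(d, n_within) {
  cells <- if (n_within == 0) rep(1, nrow(d))
           else interaction(d[paste0("w", seq_len(n_within))], drop = FALSE)
  counts <- table(d$subject, cells)
  if (any(counts != 1))
    stopf("unbalanced data: each subject needs exactly one response per
 within-subject cell")
  subj_group <- table(d$g[!duplicated(d$subject)])
  if (length(unique(subj_group)) != 1)
    stopf("unbalanced data: unequal group sizes")
  invisible(TRUE)
}

#' Independent two-sample Student's t-test
#'
#' Pooled-variance t with a two-sided p value.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return List: `t`, `df`, `p`.
#' @export
independent_ttest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("need >= 2 values per sample")
  if (stats::var(x) + stats::var(y) == 0)
    stopf("zero pooled variance")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
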