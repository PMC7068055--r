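#' Synchronize trial exclusions across modalities
#'
#' A trial excluded from either the EEG or the pupil preprocessing is
#' excluded from both analyses: the joint mask is the logical AND of the two
#' inclusion masks over the identical trial list.
#'
#' @param eeg_mask,pupil_mask logical inclusion vectors of equal length.
#' @return Logical joint inclusion mask.
#' @export
synchronize_trial_exclusions <- function(eeg_mask, pupil_mask) {
  if (length(eeg_mask) != length(pupil_mask))
    stopf("mask length mismatch (%d vs %d)", length(eeg_mask),
          length(pupil_mask))
  joint <- eeg_mask & pupil_mask
  if (!any(joint)) stopf("no retained trials after synchronization")
  joint
}

#' Preprocess one synthetic subject's pupil recording
#'
#' Calibration to mm, velocity-based blink masking (union with the device
#' flags), 2-s epoching with baseline subtraction and binocular averaging,
#' and the absolute baseline-diameter summary.
#'
#' @param subject a `synthetic_subject`.
#' @param window,baseline epoch definition, ms.
#' @param velocity_threshold,pre_pad_ms,post_pad_ms,smooth_samples blink
#'   detector settings, see [detect_blinks()].
#' @return List: `epochs` (pooled `pdr_epoch_set` across blocks),
#'   `baseline_mm` (subject mean absolute baseline diameter).
#' @export
preprocess_subject_pupil <- function(subject, window = c(-200, 1800),
                                     baseline = c(-200, 0),
                                     velocity_threshold = 20,
                                     pre_pad_ms = 50, post_pad_ms = 100,
                                     smooth_samples = 11) {
  fs <- subject$fs
  parts <- lapply(subject$blocks, function(blk) {
    cl <- calibrate_counts_to_mm(blk$pupil$left_counts, subject$calibration)
    cr <- calibrate_counts_to_mm(blk$pupil$right_counts, subject$calibration)
    bl <- detect_blinks(cl$mm, fs, velocity_threshold, pre_pad_ms,
                        post_pad_ms, smooth_samples,
                        device_blinks = blk$pupil$blink_flag_left)
    br <- detect_blinks(cr$mm, fs, velocity_threshold, pre_pad_ms,
                        post_pad_ms, smooth_samples,
                        device_blinks = blk$pupil$blink_flag_right)
    epoch_baseline_average(cl$mm, cr$mm,
                           cl$valid & !bl$mask, cr$valid & !br$mask,
                           blk$events$onset_sample, fs,
                           window = window, baseline = baseline,
                           trial_info = blk$events[, c("block_index",
                                                       "trial_index",
                                                       "trial_type")])
  })
  epochs <- structure(list(
    data = do.call(rbind, lapply(parts, `[[`, "data")),
    time_ms = parts[[1]]$time_ms,
    mask = { m <- do.call(rbind, lapply(parts, `[[`, "mask"))
             m$trial <- seq_len(nrow(m)); m },
    baseline_mm = unlist(lapply(parts, `[[`, "baseline_mm")),
    fs = fs), class = "pdr_epoch_set")
  list(epochs = epochs, baseline_mm = baseline_diameter_summary(epochs))
}

# NA-aware condition averaging of pupil epochs under a joint mask.
average_pupil_by_condition <- function(epochs, include) {
  keep <- epochs$mask$included & include
  conds <- unique(epochs$mask$trial_type)
  out <- matrix(NA_real_, length(conds), length(epochs$time_ms),
                dimnames = list(conds, NULL))
  for (ci in seq_along(conds)) {
    sel <- which(keep & epochs$mask$trial_type == conds[ci])
    if (length(sel) == 0) stopf("no retained pupil trials for '%s'",
                                conds[ci])
    out[ci, ] <- colMeans(epochs$data[sel, , drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Run the full oddball EEG + pupillometry analysis on a synthetic cohort
#'
#' End-to-end orchestration: cohort synthesis, per-subject EEG and pupil
#' preprocessing, cross-modal synchronization of trial exclusions,
#' per-group ERP temporal PCA and pooled pupil PCA (component counts by
#' Horn's parallel test unless given), component identification, difference
#' amplitudes, mixed frequentist and Bayesian ANOVAs with inclusion Bayes
#' factors, follow-up JZS t-tests on the pupil components, and the
#' observed-vs-predicted baseline diameter comparison.
#'
#' Stage parameters default to the study's values; cohort/design sizes are
#' arguments so that reduced problem sizes can be analyzed with identical
#' code.
#'
#' @param n_per_group subjects per group.
#' @param config oddball design, see [design_config()].
#' @param seed master seed; every stage derives its stream from it.
#' @param fs sampling rate, Hz.
#' @param erp_templates,pdr_templates component templates.
#' @param K_eeg,K_pupil component counts (`NULL`: Horn's parallel test).
#' @param epsilon geomin constant.
#' @param iterations Bayesian ANOVA Monte Carlo draws.
#' @param n_starts geomin random restarts.
#' @param ages mean ages (years) used for the baseline predictions, named
#'   `adults`/`children`.
#' @param ... passed to [generate_cohort()] (e.g. `montage`).
#' @return A `pipeline_report` list with per-stage tables.
#' @export
run_full_analysis <- function(n_per_group = 32L, config = design_config(),
                              seed = 1L, fs = 500,
                              erp_templates = component_templates("eeg"),
                              pdr_templates = component_templates("pupil"),
                              K_eeg = NULL, K_pupil = NULL,
                              epsilon = 0.5, iterations = 50000,
                              n_starts = 30,
                              ages = c(adults = 26.5, children = 8.8),
                              ...) {
  cohort <- generate_cohort(n_per_group, config = config, seed = seed,
                            fs = fs, ...)
  n <- length(cohort$subjects)
  avg_list <- vector("list", n)
  pupil_avg <- NULL
  baselines <- numeric(n)
  exclusion_log <- list()
  for (i in seq_len(n)) {
    sub <- cohort$subjects[[i]]
    ee <- preprocess_subject_eeg(sub, ica_seed = child_seed(seed, 5000 + i))
    pp <- preprocess_subject_pupil(sub)
    joint <- synchronize_trial_exclusions(ee$epochs$mask$included,
                                          pp$epochs$mask$included)
    include <- joint & ee$include_design
    avg_list[[i]] <- average_by_condition(ee$epochs, include)
    pa <- average_pupil_by_condition(pp$epochs, include)
    if (is.null(pupil_avg))
      pupil_avg <- array(NA_real_, c(n, nrow(pa), ncol(pa)),
                         dimnames = list(NULL, rownames(pa), NULL))
    pupil_avg[i, , ] <- pa[dimnames(pupil_avg)[[2]], ]
    baselines[i] <- pp$baseline_mm
    exclusion_log[[i]] <- data.frame(
      subject = i,
      total = length(joint),
      eeg_excluded = sum(!ee$epochs$mask$included),
      pupil_excluded = sum(!pp$epochs$mask$included),
      joint_retained = sum(joint),
      analyzed = sum(include))
  }
  groups <- cohort$manifest$group
  acohort <- assemble_average_cohort(avg_list, groups)
  acohort$pupil <- pupil_avg
  acohort$time_pdr <- NULL

  # per-group ERP PCA
  erp_results <- list()
  for (g in unique(groups)) {
    om <- build_observation_matrix(acohort, "eeg", scope = g)
    K <- K_eeg %||% as.integer(horns_parallel_test(
      om, seed = child_seed(seed, 7001)))
    K <- max(K, 1L)
    fit <- fit_temporal_pca(om, K, epsilon = epsilon, n_starts = n_starts,
                            seed = child_seed(seed, 7002))
    assign_map <- identify_components(fit, erp_templates, resolve_ambiguity = TRUE)
    erp_results[[g]] <- list(om = om, K = K, fit = fit,
                             assignment = assign_map)
  }

  # difference-amplitude inference per template
  amp_tables <- list()
  inference <- list()
  for (ti in seq_len(nrow(erp_templates))) {
    tpl <- erp_templates[ti, ]
    per_group <- lapply(names(erp_results), function(g) {
      k <- erp_results[[g]]$assignment[tpl$name]
      if (is.na(k)) return(NULL)
      component_amplitudes(erp_results[[g]]$fit, k,
                           electrode = tpl$electrode)
    })
    tab <- do.call(rbind, per_group)
    if (is.null(tab)) next
    tab$component <- tpl$name
    amp_tables[[tpl$name]] <- tab
    long <- tab[tab$condition != "standard",
                c("subject", "group", "condition", "difference")]
    names(long)[3:4] <- c("emotion", "value")
    long$emotion <- ifelse(long$emotion == "novel_emotional",
                           "emotional", "neutral")
    if (length(unique(long$group)) == 2 &&
        all(table(long$subject) == 2)) {
      freq <- mixed_anova(long)
      bay <- bayes_anova(long, iterations = iterations,
                         seed = child_seed(seed, 8000 + ti))
      inference[[tpl$name]] <- list(
        anova = freq, bayes = bay,
        bf_incl_interaction = inclusion_bf(bay, "group:emotion"))
    }
  }

  # pooled pupil PCA on both groups
  pup_time <- preprocess_time_axis(fs, c(-200, 1800))
  acohort$time_pdr <- pup_time
  om_p <- build_observation_matrix(acohort, "pupil", scope = "pooled")
  Kp <- K_pupil %||% as.integer(horns_parallel_test(
    om_p, seed = child_seed(seed, 7003)))
  Kp <- max(Kp, 1L)
  fit_p <- fit_temporal_pca(om_p, Kp, epsilon = epsilon,
                            n_starts = n_starts,
                            seed = child_seed(seed, 7004))
  assign_p <- identify_components(fit_p, pdr_templates, resolve_ambiguity = TRUE)

  pupil_inference <- NULL
  if (!anyNA(assign_p) && length(assign_p) == 2) {
    lab <- fit_p$labels
    rows <- lab$condition != "standard"
    score_tab <- do.call(rbind, lapply(names(assign_p), function(nm) {
      data.frame(subject = lab$subject[rows], group = lab$group[rows],
                 emotion = ifelse(lab$condition[rows] == "novel_emotional",
                                  "emotional", "neutral"),
                 component = nm,
                 value = fit_p$scores[rows, assign_p[nm]],
                 stringsAsFactors = FALSE)
    }))
    freq_p <- mixed_anova(score_tab, within = c("emotion", "component"))
    bay_p <- bayes_anova(score_tab, within = c("emotion", "component"),
                         iterations = iterations,
                         seed = child_seed(seed, 8100))
    follow <- lapply(names(assign_p), function(nm) {
      w <- score_tab[score_tab$component == nm, ]
      diffs <- w$value[w$emotion == "emotional"][order(w$subject[w$emotion == "emotional"])] -
        w$value[w$emotion == "neutral"][order(w$subject[w$emotion == "neutral"])]
      list(component = nm, bf10 = jzs_ttest_bf(diffs),
           t = unname(stats::t.test(diffs)$statistic),
           p = stats::t.test(diffs)$p.value)
    })
    pupil_inference <- list(
      anova = freq_p, bayes = bay_p, followup = follow,
      component_effect_interpretable = FALSE,
      bf_incl = sapply(c("emotion", "group", "group:emotion",
                         "emotion:component", "group:component",
                         "group:emotion:component"),
                       function(e) inclusion_bf(bay_p, e)))
  }

  # baseline diameter: observed vs unified-model prediction
  base_tab <- data.frame(group = groups, observed = baselines)
  base_summary <- do.call(rbind, lapply(unique(groups), function(g) {
    pred <- predict_diameter(study_viewing_conditions(ages[[g]]))
    obs <- mean(base_tab$observed[base_tab$group == g])
    data.frame(group = g, observed_mm = obs, predicted_mm = pred,
               percent_deviation = percent_deviation(obs, pred))
  }))

  structure(list(
    seed = seed,
    session = session_summary(cohort$subjects[[1]]$sequence),
    exclusions = do.call(rbind, exclusion_log),
    erp = erp_results, amplitudes = amp_tables, inference = inference,
    pupil_fit = fit_p, pupil_assignment = assign_p,
    pupil_inference = pupil_inference,
    baseline = base_summary), class = "pipeline_report")
}

preprocess_time_axis <- function(fs, window) {
  seq(round(window[1] * fs / 1000),
      round(window[2] * fs / 1000) - 1L) * 1000 / fs
}
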