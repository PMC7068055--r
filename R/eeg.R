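#' Cut stimulus-locked epochs and subtract the pre-stimulus baseline
#'
#' Epochs are half-open `[from, to)` windows at the recording's sampling
#' rate, sample 0 at stimulus onset. Events whose window leaves the
#' recording are dropped with a recorded reason. The baseline-window mean is
#' subtracted per epoch and channel.
#'
#' @param eeg channels x samples matrix (uV).
#' @param onset_samples event onsets (sample indices).
#' @param fs sampling rate, Hz.
#' @param window epoch window in ms.
#' @param baseline baseline window in ms.
#' @param trial_info optional per-event data frame carried into the mask.
#' @return An `epoch_set`: `data` trial x channel x time array, `time_ms`,
#'   `channels`, `mask` (trial, included, reason), `fs`.
#' @export
epoch_and_baseline <- function(eeg, onset_samples, fs,
                               window = c(-200, 800),
                               baseline = c(-200, 0),
                               trial_info = NULL) {
  rel <- seq(round(window[1] * fs / 1000),
             round(window[2] * fs / 1000) - 1L)
  time_ms <- rel * 1000 / fs
  base_idx <- which(time_ms >= baseline[1] & time_ms < baseline[2])
  n_tr <- length(onset_samples)
  chans <- rownames(eeg) %||% paste0("ch", seq_len(nrow(eeg)))
  data <- array(NA_real_, c(n_tr, nrow(eeg), length(rel)),
                dimnames = list(NULL, chans, NULL))
  included <- logical(n_tr)
  reason <- rep(NA_character_, n_tr)
  for (i in seq_len(n_tr)) {
    idx <- onset_samples[i] + rel
    if (idx[1] < 1 || idx[length(idx)] > ncol(eeg)) {
      reason[i] <- "window out of bounds"; next
    }
    ep <- eeg[, idx, drop = FALSE]
    ep <- ep - rowMeans(ep[, base_idx, drop = FALSE])
    data[i, , ] <- ep
    included[i] <- TRUE
  }
  mask <- data.frame(trial = seq_len(n_tr), included = included,
                     reason = reason, stringsAsFactors = FALSE)
  if (!is.null(trial_info)) mask <- cbind(mask, trial_info)
  structure(list(data = data, time_ms = time_ms, channels = chans,
                 mask = mask, fs = fs), class = "epoch_set")
}

#' Exclude epochs with excessive amplitude range
#'
#' An epoch is excluded when the peak-to-peak range (max minus min within
#' the epoch) of any channel strictly exceeds the threshold; a range of
#' exactly the threshold is retained.
#'
#' @param epochs an `epoch_set` (baselined).
#' @param threshold_uv peak-to-peak threshold in uV.
#' @return The `epoch_set` with its mask updated (reason
#'   `"amplitude range exceeded"`).
#' @export
reject_amplitude_artifacts <- function(epochs, threshold_uv = 150) {
  for (i in which(epochs$mask$included)) {
    rng <- apply(epochs$data[i, , , drop = FALSE], 2,
                 function(ch) max(ch) - min(ch))
    if (any(rng > threshold_uv)) {
      epochs$mask$included[i] <- FALSE
      epochs$mask$reason[i] <- "amplitude range exceeded"
    }
  }
  epochs
}

#' Select the standard trials entering the analysis
#'
#' Excludes, per block, the first two standard trials and the two standards
#' immediately following each novel (union of the two rules); novels are
#' always included.
#'
#' @param sequence a `trial_sequence`.
#' @param n_lead_in number of initial standards excluded per block.
#' @param n_post_novel number of standards excluded after each novel.
#' @return Logical inclusion vector aligned with the rows of `sequence`.
#' @export
select_analysis_standards <- function(sequence, n_lead_in = 2L,
                                      n_post_novel = 2L) {
  include <- rep(TRUE, nrow(sequence))
  for (b in unique(sequence$block_index)) {
    rows <- which(sequence$block_index == b)
    std <- rows[sequence$trial_type[rows] == "standard"]
    include[utils::head(std, n_lead_in)] <- FALSE
    for (q in rows[sequence$trial_type[rows] != "standard"]) {
      post <- std[std > q]
      include[utils::head(post, n_post_novel)] <- FALSE
    }
  }
  include
}

#' Average retained epochs by condition
#'
#' @param epochs an `epoch_set` with a `trial_type` column in its mask.
#' @param include optional additional logical inclusion vector (e.g. the
#'   design-based standard selection or the cross-modal joint mask).
#' @return An `average_set` for one subject: `data` condition x channel x
#'   time array, `n_trials` per condition, `time_ms`, `channels`.
#' @export
average_by_condition <- function(epochs, include = NULL) {
  keep <- epochs$mask$included
  if (!is.null(include)) keep <- keep & include
  cond <- epochs$mask$trial_type
  if (is.null(cond)) stopf("epochs lack trial_type information")
  levels <- unique(cond)
  out <- array(NA_real_, c(length(levels), dim(epochs$data)[2],
                           dim(epochs$data)[3]),
               dimnames = list(levels, epochs$channels, NULL))
  n_trials <- setNames(integer(length(levels)), levels)
  for (ci in seq_along(levels)) {
    sel <- which(keep & cond == levels[ci])
    if (length(sel) == 0)
      stopf("no retained trials for condition '%s'", levels[ci])
    n_trials[ci] <- length(sel)
    out[ci, , ] <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  }
  structure(list(data = out, n_trials = n_trials, time_ms = epochs$time_ms,
                 channels = epochs$channels, conditions = levels,
                 fs = epochs$fs), class = "average_set")
}

#' Preprocess one synthetic subject's EEG end to end
#'
#' Runs the full single-subject chain: 0.1-40 Hz filtering of each block, a
#' parallel 1-40 Hz copy for ICA estimation, EOG-correlation ocular
#' cleaning, epoching with baseline correction, 150-uV artifact rejection,
#' design-based standard selection, and condition averaging. Blocks are
#' filtered and cleaned independently (they are separate recordings), then
#' their epochs pooled.
#'
#' @param subject a `synthetic_subject`.
#' @param highpass_hz,lowpass_hz,ica_highpass_hz filter cutoffs.
#' @param highpass_order,lowpass_order filter orders.
#' @param eog_threshold ocular flagging threshold.
#' @param reject_uv amplitude rejection threshold.
#' @param window,baseline epoch definition in ms.
#' @param ica_seed seed for the ICA initialization.
#' @param run_ica set `FALSE` to skip ocular cleaning (e.g. noiseless
#'   ground-truth checks, where rank-deficient data admit no full ICA).
#' @return List: `epochs` (pooled `epoch_set`), `averages` (`average_set`),
#'   `include_design` (standard-selection mask aligned with epochs),
#'   `ica_reports` per block, `sequence`.
#' @export
preprocess_subject_eeg <- function(subject,
                                   highpass_hz = 0.1, highpass_order = 8250,
                                   lowpass_hz = 40, lowpass_order = 166,
                                   ica_highpass_hz = 1,
                                   eog_threshold = 0.8,
                                   reject_uv = 150,
                                   window = c(-200, 800),
                                   baseline = c(-200, 0),
                                   ica_seed = 1L,
                                   run_ica = TRUE) {
  fs <- subject$fs
  hp <- design_windowed_sinc("highpass", highpass_hz, highpass_order,
                             fs = fs)
  hp1 <- design_windowed_sinc("highpass", ica_highpass_hz, highpass_order,
                              fs = fs)
  lp <- design_windowed_sinc("lowpass", lowpass_hz, lowpass_order, fs = fs)
  scalp <- eeg_channels(subject$montage)
  eogs <- eog_channels(subject$montage)

  ep_list <- list()
  info_list <- list()
  ica_reports <- list()
  for (bi in seq_along(subject$blocks)) {
    blk <- subject$blocks[[bi]]
    x01 <- apply_filter(apply_filter(blk$eeg, hp), lp)
    if (run_ica) {
      x1 <- apply_filter(apply_filter(blk$eeg, hp1), lp)
      clean <- ica_ocular_clean(x1[scalp, , drop = FALSE],
                                x01[scalp, , drop = FALSE],
                                x1[eogs, , drop = FALSE],
                                threshold = eog_threshold,
                                seed = child_seed(ica_seed, bi))
      ica_reports[[bi]] <- clean[c("flagged", "fraction_removed")]
      cleaned <- clean$cleaned
    } else {
      cleaned <- x01[scalp, , drop = FALSE]
    }
    ep <- epoch_and_baseline(cleaned, blk$events$onset_sample, fs,
                             window = window, baseline = baseline,
                             trial_info = blk$events[, c("block_index",
                                                         "trial_index",
                                                         "trial_type")])
    ep <- reject_amplitude_artifacts(ep, reject_uv)
    ep_list[[bi]] <- ep
  }
  epochs <- pool_epoch_sets(ep_list)
  seqn <- do.call(rbind, lapply(subject$blocks, function(b)
    b$events[, setdiff(names(b$events), "onset_sample")]))
  class(seqn) <- c("trial_sequence", "data.frame")
  include_design <- select_analysis_standards(seqn)
  averages <- average_by_condition(epochs, include_design)
  list(epochs = epochs, averages = averages,
       include_design = include_design,
       ica_reports = ica_reports, sequence = seqn)
}

pool_epoch_sets <- function(eps) {
  stopifnot(length(eps) >= 1)
  data <- do.call(abind3, lapply(eps, `[[`, "data"))
  mask <- do.call(rbind, lapply(eps, `[[`, "mask"))
  mask$trial <- seq_len(nrow(mask))
  structure(list(data = data, time_ms = eps[[1]]$time_ms,
                 channels = eps[[1]]$channels, mask = mask,
                 fs = eps[[1]]$fs), class = "epoch_set")
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1],
                                      numeric(1))), d[2], d[3]),
               dimnames = c(list(NULL), dimnames(arrs[[1]])[2:3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Stack single-subject averages into a cohort array
#'
#' @param avg_list list of per-subject `average_set`s (identical channels,
#'   time axis, conditions).
#' @param groups character vector of group labels, one per subject.
#' @return An `average_cohort` (see [simulate_average_cohort()]) without
#'   ground-truth annotations.
#' @export
assemble_average_cohort <- function(avg_list, groups) {
  stopifnot(length(avg_list) == length(groups))
  a1 <- avg_list[[1]]
  conds <- a1$conditions
  eeg <- array(NA_real_, c(length(avg_list), length(conds),
                           length(a1$channels), length(a1$time_ms)),
               dimnames = list(NULL, conds, a1$channels, NULL))
  for (i in seq_along(avg_list)) {
    stopifnot(identical(avg_list[[i]]$conditions, conds))
    eeg[i, , , ] <- avg_list[[i]]$data
  }
  structure(list(eeg = eeg, pupil = NULL,
                 subjects = data.frame(subject = seq_along(avg_list),
                                       group = groups),
                 channels = a1$channels, time_eeg = a1$time_ms,
                 time_pdr = NULL, conditions = conds, truths = NULL,
                 fs = a1$fs),
            class = "average_cohort")
}
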