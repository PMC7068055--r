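#' Pupil count calibration
#'
#' Eye trackers report pupil size in arbitrary device counts; a reference
#' recording of a target of known diameter converts counts to mm. In
#' diameter mode counts are proportional to diameter; in area mode counts
#' are proportional to area, so diameter follows a square-root law.
#'
#' @param counts numeric vector of device counts.
#' @param calibration list with `mode` (`"diameter"` or `"area"`),
#'   `reference_counts`, `reference_mm`.
#' @return List with `mm` (diameter in mm) and `valid` (FALSE where counts
#'   are zero or negative, e.g. during blinks).
#' @export
calibrate_counts_to_mm <- function(counts, calibration = default_calibration()) {
  if (calibration$reference_counts <= 0 || calibration$reference_mm <= 0)
    stopf("calibration constants must be positive")
  mm <- switch(calibration$mode,
    diameter = counts * (calibration$reference_mm /
                           calibration$reference_counts),
    area = calibration$reference_mm *
      sqrt(pmax(counts, 0) / calibration$reference_counts),
    stopf("unknown calibration mode '%s'", calibration$mode))
  list(mm = mm, valid = counts > 0)
}

#' @rdname calibrate_counts_to_mm
#' @export
default_calibration <- function() {
  list(mode = "diameter", reference_counts = 4000, reference_mm = 5)
}

# Inverse of the calibration, used by the synthetic generator.
mm_to_counts <- function(mm, calibration = default_calibration()) {
  switch(calibration$mode,
    diameter = mm * (calibration$reference_counts /
                       calibration$reference_mm),
    area = calibration$reference_counts * (mm / calibration$reference_mm)^2)
}

#' Velocity-based blink detection
#'
#' Marks samples invalid where the absolute derivative of the (moving-average
#' smoothed) diameter strictly exceeds the velocity threshold, unions them
#' with device-marked blink samples, and dilates the union by the pre/post
#' padding intervals. Partial blinks missed by the tracker are caught by the
#' velocity rule.
#'
#' @param diameter_mm one eye's diameter trace (mm).
#' @param fs sampling rate, Hz.
#' @param velocity_threshold mm/s; strictly-exceeding rule.
#' @param pre_pad_ms,post_pad_ms dilation before/after each masked interval.
#' @param smooth_samples width of the centered moving average applied before
#'   differentiation (1 = no smoothing).
#' @param device_blinks logical vector of tracker-marked blink samples.
#' @return List: `mask` (logical, TRUE = invalid) and `intervals` (data
#'   frame of masked runs, sample indices).
#' @export
detect_blinks <- function(diameter_mm, fs,
                          velocity_threshold = 20,
                          pre_pad_ms = 50, post_pad_ms = 100,
                          smooth_samples = 11,
                          device_blinks = NULL) {
  n <- length(diameter_mm)
  sm <- if (smooth_samples > 1) {
    k <- rep(1 / smooth_samples, smooth_samples)
    as.numeric(stats::filter(diameter_mm, k, sides = 2))
  } else diameter_mm
  v <- c(NA, diff(sm)) * fs                 # mm/s at each sample
  fast <- !is.na(v) & abs(v) > velocity_threshold
  fast[which(fast) - 1L] <- TRUE            # flag both samples of the step
  flagged <- fast
  if (!is.null(device_blinks)) flagged <- flagged | device_blinks
  mask <- dilate_mask(flagged, round(pre_pad_ms * fs / 1000),
                      round(post_pad_ms * fs / 1000))
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  intervals <- data.frame(onset_sample = starts[runs$values],
                          offset_sample = ends[runs$values])
  list(mask = mask, intervals = intervals)
}

dilate_mask <- function(flag, before, after) {
  n <- length(flag)
  out <- logical(n)
  idx <- which(flag)
  if (length(idx) == 0) return(out)
  for (i in idx) {
    out[max(1, i - before):min(n, i + after)] <- TRUE
  }
  out
}

#' Epoch, baseline-correct and binocularly average pupil traces
#'
#' Cuts 2-s epochs around each event, excludes trials where either eye is
#' invalid throughout the whole trial (closed or unrecorded) or where the
#' epoch window leaves the recording, subtracts the per-eye pre-stimulus
#' baseline mean, and averages the two eyes sample-wise. Blink-masked
#' samples are excluded (NA), not interpolated.
#'
#' @param left_mm,right_mm calibrated diameter traces (mm).
#' @param valid_left,valid_right logical validity masks (TRUE = usable),
#'   typically `!detect_blinks(...)$mask & calibrated$valid`.
#' @param onset_samples event onsets (sample indices).
#' @param fs sampling rate, Hz.
#' @param window epoch window in ms, half-open `[from, to)`.
#' @param baseline baseline window in ms.
#' @param trial_info optional data frame (one row per event) carried into
#'   the mask table.
#' @return A `pdr_epoch_set`: `data` trials x time matrix of binocular-mean
#'   baseline-subtracted dilation (mm, NA where both eyes masked),
#'   `time_ms`, `mask` (trial, included, reason), and `baseline_mm`
#'   (per-trial absolute baseline diameter, mean of eyes).
#' @export
epoch_baseline_average <- function(left_mm, right_mm,
                                   valid_left, valid_right,
                                   onset_samples, fs,
                                   window = c(-200, 1800),
                                   baseline = c(-200, 0),
                                   trial_info = NULL) {
  n <- length(left_mm)
  rel <- seq(round(window[1] * fs / 1000),
             round(window[2] * fs / 1000) - 1L)
  time_ms <- rel * 1000 / fs
  base_idx <- which(time_ms >= baseline[1] & time_ms < baseline[2])
  n_tr <- length(onset_samples)
  data <- matrix(NA_real_, n_tr, length(rel))
  baseline_mm <- rep(NA_real_, n_tr)
  included <- logical(n_tr)
  reason <- rep(NA_character_, n_tr)
  for (i in seq_len(n_tr)) {
    idx <- onset_samples[i] + rel
    if (idx[1] < 1 || idx[length(idx)] > n) {
      reason[i] <- "window out of bounds"; next
    }
    vl <- valid_left[idx]; vr <- valid_right[idx]
    if (!any(vl) || !any(vr)) {
      reason[i] <- "eye closed/unrecorded"; next
    }
    l <- ifelse(vl, left_mm[idx], NA_real_)
    r <- ifelse(vr, right_mm[idx], NA_real_)
    bl <- mean(l[base_idx], na.rm = TRUE)
    br <- mean(r[base_idx], na.rm = TRUE)
    if (is.nan(bl) || is.nan(br)) {
      reason[i] <- "no valid baseline"; next
    }
    eyes <- rbind(l - bl, r - br)
    data[i, ] <- colMeans(eyes, na.rm = TRUE)  # NaN where both eyes masked
    baseline_mm[i] <- mean(c(bl, br))
    included[i] <- TRUE
  }
  data[is.nan(data)] <- NA_real_
  mask <- data.frame(trial = seq_len(n_tr), included = included,
                     reason = reason, stringsAsFactors = FALSE)
  if (!is.null(trial_info)) mask <- cbind(mask, trial_info)
  structure(list(data = data, time_ms = time_ms, mask = mask,
                 baseline_mm = baseline_mm, fs = fs),
            class = "pdr_epoch_set")
}

#' Absolute baseline pupil diameter summary
#'
#' Mean pre-stimulus absolute diameter (mm, not baseline-subtracted) over
#' retained trials of one recording; group summaries are the mean over
#' subjects.
#'
#' @param epochs a `pdr_epoch_set`.
#' @return Mean baseline diameter in mm.
#' @export
baseline_diameter_summary <- function(epochs) {
  ok <- epochs$mask$included
  if (!any(ok)) stopf("no retained trials")
  mean(epochs$baseline_mm[ok])
}
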