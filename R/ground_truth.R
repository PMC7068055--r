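#' Temporal kernels of the signal model
#'
#' ERP components use unit-peak Gaussian kernels parameterized by peak
#' latency and width (SD), so the amplitude parameter is the component's
#' peak in microvolts. Pupil components use the Erlang-family response
#' kernel standard in pupillometry, `(t/tmax)^n * exp(n * (1 - t/tmax))`,
#' unit peak at `tmax`.
#'
#' @param t_ms time axis in ms (stimulus onset at 0).
#' @param peak_ms peak latency in ms.
#' @param width_ms Gaussian SD in ms (ERP kernel).
#' @param shape shape parameter of the pupil kernel.
#' @return Numeric vector of kernel values, unit peak.
#' @export
erp_kernel <- function(t_ms, peak_ms, width_ms) {
  exp(-0.5 * ((t_ms - peak_ms) / width_ms)^2)
}

#' @rdname erp_kernel
#' @export
pdr_kernel <- function(t_ms, peak_ms, shape = 10.1) {
  h <- numeric(length(t_ms))
  pos <- t_ms > 0
  tt <- t_ms[pos] / peak_ms
  h[pos] <- tt^shape * exp(shape * (1 - tt))
  h
}

#' Ground truth for synthetic oddball cohorts
#'
#' Defaults plant the study's component structure: P2, N1 (adults only),
#' N2 (children only), early and late P3a, and LDN in the EEG, with the
#' reported group peak latencies (e.g. early P3a 230 ms in adults, 294 ms in
#' children) and emotion/group amplitude effects; a biphasic pupil dilation
#' response with early/late peaks at 640/1520 ms; and group baseline pupil
#' diameters of 4.17 mm (adults) and 5.39 mm (children).
#'
#' Amplitudes are condition-level component peaks (microvolts for EEG, mm
#' for pupil). Between-subject variation: additive Gaussian deviations on
#' every condition-level amplitude (`amp_sd` columns) and a shared Gaussian
#' latency jitter per component (`latency_sd_ms`).
#'
#' @param group `"adults"` or `"children"`.
#' @return A `ground_truth` list with elements `group`, `erp` (data frame of
#'   component parameters), `pdr` (data frame), `baseline_mm`,
#'   `baseline_sd_mm`, `noise` (list of nuisance parameters), and
#'   `ocular` (scripted blink artifact parameters).
#' @export
default_ground_truth <- function(group = c("adults", "children")) {
  group <- match.arg(group)
  a <- group == "adults"
  erp <- data.frame(
    name      = c("N1",  "P2",  "N2",  "eP3a", "lP3a", "LDN"),
    latency_ms = if (a) c(100, 186, NA, 230, 308, 702)
                 else   c(NA, 160, 240, 294, 354, 718),
    width_ms  = c(18, 20, 25, 26, 34, 60),
    electrode = c("Cz", "Cz", "Fz", "Cz", "Fz", "F4"),
    spread    = c(0.50, 0.40, 0.50, 0.50, 0.45, 0.45),
    amp_standard       = if (a) c(-2.0, 1.0, 0, 0.5, 0.3, 0.0)
                         else   c(0, 1.5, -0.5, 0.5, 0.3, 0.0),
    amp_novel_neutral  = if (a) c(-2.5, 2.0, 0, 5.0, 3.0, -0.8)
                         else   c(0, 4.0, -1.5, 7.5, 4.5, -2.5),
    amp_novel_emotional = if (a) c(-2.5, 3.0, 0, 6.5, 4.0, -0.8)
                          else   c(0, 5.0, -1.5, 9.0, 5.5, -2.5),
    amp_sd    = c(0.5, 0.6, 0.5, 1.2, 1.0, 0.6),
    latency_sd_ms = c(8, 12, 12, 20, 20, 25),
    stringsAsFactors = FALSE
  )
  erp <- erp[!is.na(erp$latency_ms), ]
  pdr <- data.frame(
    name = c("PDR_early", "PDR_late"),
    peak_ms = c(640, 1520),
    shape = c(10.1, 10.1),
    amp_standard        = if (a) c(0.010, 0.020) else c(0.008, 0.015),
    amp_novel_neutral   = if (a) c(0.050, 0.120) else c(0.035, 0.085),
    amp_novel_emotional = if (a) c(0.050, 0.155) else c(0.035, 0.120),
    amp_sd = c(0.020, 0.032),
    latency_sd_ms = c(40, 60),
    stringsAsFactors = FALSE
  )
  structure(list(
    group = group,
    erp = erp,
    pdr = pdr,
    baseline_mm = if (a) 4.17 else 5.39,
    baseline_sd_mm = 0.45,
    noise = list(
      eeg_white_sd = 8,        # uV, single-trial broadband
      eeg_pink_sd = 8,         # uV, 1/f component
      residual_sd = 0.8,       # uV, residual noise on an individual average
      pupil_noise_sd = 0.010,  # mm, per-sample measurement noise
      pupil_drift_sd = 0.0015, # mm per sample, random-walk slow drift
      pupil_residual_sd = 0.008, # mm, residual on an averaged pupil epoch
      blink_rate_per_min = 12
    ),
    ocular = list(
      blink_amp_uV = 250, blink_width_ms = 120,
      mixing = c(VEOG = 1.0, HEOG_L = 0.15, HEOG_R = 0.15,
                 Fp1 = 0.45, Fp2 = 0.45, F3 = 0.18, Fz = 0.18, F4 = 0.18,
                 F7 = 0.10, F8 = 0.10, FC1 = 0.08, FC2 = 0.08)
    )
  ), class = "ground_truth")
}
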