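#' Realize subject-level parameters from group ground truth
#'
#' Draws one subject's component amplitudes (additive Gaussian deviations
#' around the condition-level truth), component latencies (shared Gaussian
#' jitter per component) and baseline pupil diameter.
#'
#' @param truth a [default_ground_truth()] object.
#' @param seed integer seed.
#' @param between_subject_sd_scale multiply all between-subject SDs (0 gives
#'   a cohort of identical subjects).
#' @return A `ground_truth`-like list with subject-level `erp`/`pdr` tables.
#' @export
realize_subject_truth <- function(truth, seed,
                                  between_subject_sd_scale = 1) {
  with_seed(seed, {
    st <- truth
    sc <- between_subject_sd_scale
    for (tab in c("erp", "pdr")) {
      d <- st[[tab]]
      lat_col <- if (tab == "erp") "latency_ms" else "peak_ms"
      d[[lat_col]] <- d[[lat_col]] + rnorm(nrow(d), 0, sc * d$latency_sd_ms)
      for (cond in c("amp_standard", "amp_novel_neutral",
                     "amp_novel_emotional")) {
        d[[cond]] <- d[[cond]] + rnorm(nrow(d), 0, sc * d$amp_sd)
      }
      st[[tab]] <- d
    }
    st$baseline_mm <- truth$baseline_mm +
      rnorm(1, 0, sc * truth$baseline_sd_mm)
    st
  })
}

amp_column <- function(trial_type) {
  c(standard = "amp_standard",
    novel_emotional = "amp_novel_emotional",
    novel_neutral = "amp_novel_neutral")[trial_type]
}

# Noiseless evoked EEG for one block: sum over events and components of
# amplitude * kernel(t - onset - latency) * topography.
evoked_eeg_block <- function(events, subj_truth, montage, fs, n_samples) {
  chans <- eeg_channels(montage)
  out <- matrix(0, nrow = length(chans), ncol = n_samples,
                dimnames = list(chans, NULL))
  erp <- subj_truth$erp
  if (nrow(erp) == 0 || nrow(events) == 0) return(out)
  topo <- lapply(seq_len(nrow(erp)), function(i)
    topography_weights(erp$electrode[i], erp$spread[i], montage))
  for (i in seq_len(nrow(erp))) {
    support <- ceiling(5 * erp$width_ms[i] * fs / 1000)
    center <- round(erp$latency_ms[i] * fs / 1000)
    rel <- (center - support):(center + support)
    kern <- erp_kernel(rel * 1000 / fs, erp$latency_ms[i], erp$width_ms[i])
    for (e in seq_len(nrow(events))) {
      a <- erp[[amp_column(events$trial_type[e])]][i]
      if (a == 0) next
      idx <- events$onset_sample[e] + rel
      ok <- idx >= 1 & idx <= n_samples
      if (!any(ok)) next
      out[, idx[ok]] <- out[, idx[ok]] + outer(topo[[i]], a * kern[ok])
    }
  }
  out
}

# 1/f-shaped noise via spectral shaping of white noise, unit SD.
# Shaped at a 5-smooth length (mixed-radix FFT stays n log n) and truncated.
pink_noise <- function(n) {
  n_out <- n
  n <- stats::nextn(n, c(2, 3, 5))
  white <- rnorm(n)
  f <- seq(0, 1, length.out = floor(n / 2) + 1)
  scale <- c(0, 1 / sqrt(f[-1]))
  x <- fft(white)
  idx <- seq_along(scale)
  x[idx] <- x[idx] * scale
  if (n %% 2 == 0) {
    x[(n / 2 + 2):n] <- Conj(x[(n / 2):2])
  } else {
    x[(floor(n / 2) + 2):n] <- Conj(x[(floor(n / 2) + 1):2])
  }
  out <- Re(fft(x, inverse = TRUE))[seq_len(n_out)] / n
  out / stats::sd(out)
}

# Scripted blink source for one block: smooth unit-peak bumps at Poisson
# times; returns the source series plus the blink interval table.
blink_source <- function(n_samples, fs, rate_per_min, width_ms) {
  dur_s <- n_samples / fs
  n_blinks <- rpois(1, rate_per_min * dur_s / 60)
  src <- numeric(n_samples)
  if (n_blinks == 0) {
    return(list(source = src,
                blinks = data.frame(onset_sample = integer(0),
                                    offset_sample = integer(0))))
  }
  centers <- sort(sample.int(n_samples, n_blinks))
  half <- ceiling(2.5 * width_ms * fs / 1000)
  for (cc in centers) {
    rel <- max(1, cc - half):min(n_samples, cc + half)
    src[rel] <- src[rel] +
      exp(-0.5 * ((rel - cc) * 1000 / fs / width_ms)^2)
  }
  list(source = src,
       blinks = data.frame(onset_sample = pmax(1, centers - half),
                           offset_sample = pmin(n_samples, centers + half)))
}

#' Synthesize one subject's continuous EEG and pupil recordings
#'
#' Implements the additive signal model: EEG is the sum over events and
#' components of amplitude x kernel x topography plus white and 1/f noise
#' and a scripted ocular (blink) source mixed into EOG and frontal channels;
#' pupil diameter is baseline plus the event-locked biphasic dilation
#' response plus a random-walk drift, measurement noise and scripted blinks
#' (full blinks are device-flagged and zeroed, partial blinks only produce a
#' fast dip that the velocity detector must find).
#'
#' @param sequence a `trial_sequence` (one or more blocks).
#' @param truth group-level [default_ground_truth()].
#' @param seed integer seed.
#' @param fs sampling rate, Hz (EEG and pupil are synchronized).
#' @param montage electrode table from [default_montage()].
#' @param pad_ms recording time before the first and after the last onset.
#' @param include_noise,include_ocular switch nuisance structure off for
#'   noiseless ground-truth checks.
#' @param between_subject_sd_scale see [realize_subject_truth()].
#' @param calibration pupil count calibration, see [calibrate_counts_to_mm()].
#' @return A `synthetic_subject` list: `group`, realized `truth`, `fs`,
#'   `montage`, `calibration`, `ocular_mixing`, and `blocks` (per block:
#'   `eeg` channels x samples matrix in uV including EOG rows, `events`
#'   table with `onset_sample`, `pupil` data frame in device counts with
#'   blink flags, `ocular_source`, `evoked` noiseless EEG, and the noiseless
#'   `pupil_mm` per eye).
#' @export
synthesize_subject <- function(sequence, truth, seed = 1L, fs = 500,
                               montage = default_montage(),
                               pad_ms = 3000,
                               include_noise = TRUE,
                               include_ocular = TRUE,
                               between_subject_sd_scale = 1,
                               calibration = default_calibration()) {
  st <- realize_subject_truth(truth, child_seed(seed, 1),
                              between_subject_sd_scale)
  chans <- eeg_channels(montage)
  eogs <- eog_channels(montage)
  mix <- setNames(numeric(length(chans) + length(eogs)), c(chans, eogs))
  mm <- truth$ocular$mixing
  mix[names(mm)[names(mm) %in% names(mix)]] <-
    mm[names(mm) %in% names(mix)]

  blocks <- with_seed(child_seed(seed, 2), {
    lapply(unique(sequence$block_index), function(b) {
      ev <- sequence[sequence$block_index == b, , drop = FALSE]
      ev$onset_sample <- round((ev$onset_ms + pad_ms) * fs / 1000) + 1L
      n_samples <- max(ev$onset_sample) + round((2500 + pad_ms) * fs / 1000)

      evoked <- evoked_eeg_block(ev, st, montage, fs, n_samples)
      eeg <- rbind(evoked,
                   matrix(0, length(eogs), n_samples,
                          dimnames = list(eogs, NULL)))
      ns <- truth$noise
      if (include_noise && (ns$eeg_white_sd > 0 || ns$eeg_pink_sd > 0)) {
        for (ch in seq_len(nrow(eeg))) {
          eeg[ch, ] <- eeg[ch, ] + rnorm(n_samples, 0, ns$eeg_white_sd) +
            ns$eeg_pink_sd * pink_noise(n_samples)
        }
      }
      bl <- list(source = numeric(n_samples),
                 blinks = data.frame(onset_sample = integer(0),
                                     offset_sample = integer(0)))
      if (include_ocular) {
        bl <- blink_source(n_samples, fs, ns$blink_rate_per_min,
                           truth$ocular$blink_width_ms)
        eeg <- eeg + outer(mix, truth$ocular$blink_amp_uV * bl$source)
      }

      # --- pupil ---
      t_ms <- (seq_len(n_samples) - 1) * 1000 / fs
      dil <- numeric(n_samples)
      pdr <- st$pdr
      for (i in seq_len(nrow(pdr))) {
        support <- round(4000 * fs / 1000)
        kern <- pdr_kernel((0:support) * 1000 / fs, pdr$peak_ms[i],
                           pdr$shape[i])
        for (e in seq_len(nrow(ev))) {
          a <- pdr[[amp_column(ev$trial_type[e])]][i]
          if (a == 0) next
          idx <- ev$onset_sample[e] + 0:support
          ok <- idx <= n_samples
          dil[idx[ok]] <- dil[idx[ok]] + a * kern[ok]
        }
      }
      drift <- if (include_noise && ns$pupil_drift_sd > 0) {
        d <- cumsum(rnorm(n_samples, 0, ns$pupil_drift_sd))
        d - mean(d)
      } else numeric(n_samples)
      base <- st$baseline_mm + dil + drift
      eye_noise <- function() if (include_noise)
        rnorm(n_samples, 0, ns$pupil_noise_sd) else 0
      left_mm <- base + eye_noise()
      right_mm <- base + 0.05 + eye_noise()

      flag_l <- flag_r <- rep(FALSE, n_samples)
      if (include_ocular && nrow(bl$blinks) > 0) {
        bl$blinks$type <- ifelse(runif(nrow(bl$blinks)) < 0.7,
                                 "full", "partial")
        for (k in seq_len(nrow(bl$blinks))) {
          span <- bl$blinks$onset_sample[k]:bl$blinks$offset_sample[k]
          if (bl$blinks$type[k] == "full") {  # flagged, trace lost
            left_mm[span] <- 0; right_mm[span] <- 0
            flag_l[span] <- TRUE; flag_r[span] <- TRUE
          } else {
            # partial blink: fast dip the tracker does not flag (~30 ms SD,
            # peak closing velocity ~30 mm/s); found by the velocity rule
            mid <- stats::median(span)
            w <- truth$ocular$blink_width_ms / 4
            dip <- 1.5 * exp(-0.5 * ((span - mid) * 1000 / fs / w)^2)
            left_mm[span] <- left_mm[span] - dip
            right_mm[span] <- right_mm[span] - dip
          }
        }
      }
      pupil <- data.frame(
        time_ms = t_ms,
        left_counts = mm_to_counts(pmax(left_mm, 0), calibration),
        right_counts = mm_to_counts(pmax(right_mm, 0), calibration),
        blink_flag_left = flag_l,
        blink_flag_right = flag_r
      )
      list(eeg = eeg, events = ev, pupil = pupil,
           evoked = evoked, pupil_mm = cbind(left = left_mm,
                                             right = right_mm),
           ocular_source = bl$source, blink_table = bl$blinks,
           n_samples = n_samples)
    })
  })
  structure(list(group = truth$group, truth = st, fs = fs,
                 montage = montage, calibration = calibration,
                 ocular_mixing = mix, pad_ms = pad_ms, blocks = blocks,
                 sequence = sequence),
            class = "synthetic_subject")
}

#' Generate a synthetic cohort
#'
#' Independent subjects (each with its own pseudo-randomized sound sequence,
#' as in the study) drawn around the group-level ground truth. Defaults are
#' the study's 32 subjects per group; smaller configurations are intended
#' for unit testing.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param truth_adults,truth_children group ground truths.
#' @param config design parameters, see [design_config()].
#' @param seed integer seed.
#' @param ... passed on to [synthesize_subject()].
#' @return A `synthetic_cohort` list with `subjects` (list of
#'   `synthetic_subject`), and a `manifest` data frame (subject, group, seed).
#' @export
generate_cohort <- function(n_per_group = 32L,
                            truth_adults = default_ground_truth("adults"),
                            truth_children = default_ground_truth("children"),
                            config = design_config(),
                            seed = 1L, ...) {
  if (n_per_group < 2) stopf("n_per_group must be >= 2")
  groups <- rep(c("adults", "children"), each = n_per_group)
  subjects <- vector("list", length(groups))
  manifest <- data.frame(subject = seq_along(groups), group = groups,
                         seed = NA_real_)
  for (i in seq_along(groups)) {
    s_seed <- child_seed(seed, i)
    manifest$seed[i] <- s_seed
    seqn <- generate_sound_sequence(config, seed = child_seed(s_seed, 99))
    truth <- if (groups[i] == "adults") truth_adults else truth_children
    subjects[[i]] <- synthesize_subject(seqn, truth, seed = s_seed, ...)
    subjects[[i]]$subject <- i
  }
  structure(list(subjects = subjects, manifest = manifest, config = config),
            class = "synthetic_cohort")
}

#' Simulate a cohort directly at the averaged-waveform level
#'
#' Draws per-subject, per-condition average ERPs and pupil dilation
#' responses from the same kernel model as the continuous generator,
#' replacing single-trial noise with its averaged residual
#' (`noise$residual_sd`, `noise$pupil_residual_sd`). This is the fast path
#' for parameter-recovery simulations of the PCA/jackknife/inference stages;
#' the continuous path exercises filtering, ICA and epoching.
#'
#' @param n_per_group subjects per group.
#' @param truth_adults,truth_children group ground truths.
#' @param seed integer seed.
#' @param fs sampling rate of the averaged time axes (Hz).
#' @param channels electrode subset (default: full scalp montage).
#' @param window_eeg,window_pdr epoch windows in ms, half-open `[from, to)`.
#' @param montage electrode table.
#' @param between_subject_sd_scale see [realize_subject_truth()].
#' @return An `average_cohort`: `eeg` array subject x condition x channel x
#'   time, `pupil` array subject x condition x time, `subjects` data frame,
#'   time axes, and the realized per-subject truths.
#' @export
simulate_average_cohort <- function(n_per_group = 32L,
                                    truth_adults =
                                      default_ground_truth("adults"),
                                    truth_children =
                                      default_ground_truth("children"),
                                    seed = 1L, fs = 250,
                                    channels = NULL,
                                    window_eeg = c(-200, 800),
                                    window_pdr = c(-200, 1800),
                                    montage = default_montage(),
                                    between_subject_sd_scale = 1) {
  if (n_per_group < 2) stopf("n_per_group must be >= 2")
  if (is.null(channels)) channels <- eeg_channels(montage)
  t_eeg <- seq(round(window_eeg[1] * fs / 1000),
               round(window_eeg[2] * fs / 1000) - 1L) * 1000 / fs
  t_pdr <- seq(round(window_pdr[1] * fs / 1000),
               round(window_pdr[2] * fs / 1000) - 1L) * 1000 / fs
  conds <- c("standard", "novel_emotional", "novel_neutral")
  groups <- rep(c("adults", "children"), each = n_per_group)
  n <- length(groups)
  eeg <- array(0, c(n, length(conds), length(channels), length(t_eeg)),
               dimnames = list(NULL, conds, channels, NULL))
  pup <- array(0, c(n, length(conds), length(t_pdr)),
               dimnames = list(NULL, conds, NULL))
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- if (groups[i] == "adults") truth_adults else truth_children
    st <- realize_subject_truth(truth, child_seed(seed, i),
                                between_subject_sd_scale)
    truths[[i]] <- st
    res <- with_seed(child_seed(seed, 100000 + i), {
      erp <- st$erp
      for (k in seq_len(nrow(erp))) {
        topo <- topography_weights(erp$electrode[k], erp$spread[k],
                                   montage)[channels]
        kern <- erp_kernel(t_eeg, erp$latency_ms[k], erp$width_ms[k])
        for (ci in seq_along(conds)) {
          a <- erp[[amp_column(conds[ci])]][k]
          if (a != 0)
            eeg[i, ci, , ] <- eeg[i, ci, , ] + a * outer(topo, kern)
        }
      }
      pdr <- st$pdr
      for (k in seq_len(nrow(pdr))) {
        kern <- pdr_kernel(t_pdr, pdr$peak_ms[k], pdr$shape[k])
        for (ci in seq_along(conds)) {
          a <- pdr[[amp_column(conds[ci])]][k]
          if (a != 0) pup[i, ci, ] <- pup[i, ci, ] + a * kern
        }
      }
      rsd <- truth$noise$residual_sd
      if (rsd > 0)
        eeg[i, , , ] <- eeg[i, , , ] +
          rnorm(length(conds) * length(channels) * length(t_eeg), 0, rsd)
      prsd <- truth$noise$pupil_residual_sd
      if (prsd > 0)
        pup[i, , ] <- pup[i, , ] +
          rnorm(length(conds) * length(t_pdr), 0, prsd)
      list(eeg = eeg[i, , , , drop = FALSE], pup = pup[i, , , drop = FALSE])
    })
    eeg[i, , , ] <- res$eeg
    pup[i, , ] <- res$pup
  }
  structure(list(eeg = eeg, pupil = pup,
                 subjects = data.frame(subject = seq_len(n), group = groups),
                 channels = channels, time_eeg = t_eeg, time_pdr = t_pdr,
                 conditions = conds, truths = truths, fs = fs),
            class = "average_cohort")
}
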