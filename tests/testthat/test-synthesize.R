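test_that("null ground truth yields silent EEG and a flat pupil baseline", {
  cfg <- small_design(blocks = 1L, trials = 16L, novels = 2L)
  s <- generate_sound_sequence(cfg, seed = 1)
  tr <- default_ground_truth("adults")
  tr$erp[c("amp_standard", "amp_novel_neutral",
           "amp_novel_emotional")] <- 0
  tr$pdr[c("amp_standard", "amp_novel_neutral",
           "amp_novel_emotional")] <- 0
  sub <- synthesize_subject(s, tr, seed = 1, montage = small_montage(),
                            include_noise = FALSE, include_ocular = FALSE,
                            between_subject_sd_scale = 0)
  blk <- sub$blocks[[1]]
  expect_true(all(blk$eeg == 0))
  expect_true(all(abs(blk$pupil_mm[, "left"] - tr$baseline_mm) < 1e-12))
})

test_that("the evoked signal model is linear in the amplitudes", {
  cfg <- small_design(blocks = 1L, trials = 16L, novels = 2L)
  s <- generate_sound_sequence(cfg, seed = 3)
  tr <- default_ground_truth("children")
  tr2 <- tr
  for (col in c("amp_standard", "amp_novel_neutral", "amp_novel_emotional"))
    tr2$erp[[col]] <- 2 * tr$erp[[col]]
  args <- list(sequence = s, seed = 5, montage = small_montage(),
               include_noise = FALSE, include_ocular = FALSE,
               between_subject_sd_scale = 0)
  a <- do.call(synthesize_subject, c(args, list(truth = tr)))
  b <- do.call(synthesize_subject, c(args, list(truth = tr2)))
  expect_equal(b$blocks[[1]]$eeg, 2 * a$blocks[[1]]$eeg, tolerance = 1e-12)
})

test_that("novel-minus-standard difference peaks at the planted eP3a latency", {
  # eP3a amplitude planted for novels only; closed-form check at Cz
  cfg <- small_design(blocks = 1L, trials = 30L, novels = 4L)
  s <- generate_sound_sequence(cfg, seed = 2)
  tr <- default_ground_truth("adults")
  tr$erp <- tr$erp[tr$erp$name == "eP3a", ]
  tr$erp$amp_standard <- 0
  sub <- synthesize_subject(s, tr, seed = 1, montage = small_montage(),
                            include_noise = FALSE, include_ocular = FALSE,
                            between_subject_sd_scale = 0)
  blk <- sub$blocks[[1]]
  nov <- blk$events$onset_sample[blk$events$trial_type == "novel_neutral"]
  fs <- sub$fs
  rel <- 0:(fs - 1)                      # one second after onset
  avg <- rowMeans(vapply(nov, function(o) blk$eeg["Cz", o + rel],
                         numeric(length(rel))))
  peak_ms <- rel[which.max(avg)] * 1000 / fs
  expect_equal(peak_ms, tr$erp$latency_ms, tolerance = 1000 / fs)
  expect_equal(max(avg), tr$erp$amp_novel_neutral, tolerance = 1e-6)
})

test_that("group baselines match the study means before noise", {
  expect_equal(default_ground_truth("adults")$baseline_mm, 4.17)
  expect_equal(default_ground_truth("children")$baseline_mm, 5.39)
  cfg <- small_design(blocks = 1L, trials = 10L, novels = 1L)
  s <- generate_sound_sequence(cfg, seed = 1)
  sub <- synthesize_subject(s, default_ground_truth("children"), seed = 2,
                            montage = small_montage(),
                            include_noise = FALSE, include_ocular = FALSE,
                            between_subject_sd_scale = 0)
  base <- sub$blocks[[1]]$pupil_mm[1:100, "left"]
  expect_equal(mean(base), 5.39, tolerance = 1e-9)
})

test_that("cohorts are reproducible and respect the variance-zero limit", {
  cfg <- small_design(blocks = 1L, trials = 10L, novels = 1L)
  co1 <- generate_cohort(2L, config = cfg, seed = 11,
                         montage = small_montage())
  co2 <- generate_cohort(2L, config = cfg, seed = 11,
                         montage = small_montage())
  expect_identical(co1$subjects[[1]]$blocks[[1]]$eeg,
                   co2$subjects[[1]]$blocks[[1]]$eeg)
  expect_error(generate_cohort(1L, config = cfg), "n_per_group")
  # zero between-subject variance: identical realized truths within a group
  co3 <- generate_cohort(2L, config = cfg, seed = 3,
                         montage = small_montage(),
                         between_subject_sd_scale = 0)
  expect_equal(co3$subjects[[1]]$truth$erp, co3$subjects[[2]]$truth$erp)
})

test_that("averaged-level cohorts carry the planted group structure", {
  co <- simulate_average_cohort(4L, seed = 5, fs = 250,
                                channels = recovery_channels())
  expect_equal(dim(co$eeg), c(8, 3, 9, 250))
  expect_equal(dim(co$pupil), c(8, 3, 500))
  # noiseless, zero-variance version equals the kernel model exactly
  ta <- default_ground_truth("adults")
  ta$noise$residual_sd <- 0; ta$noise$pupil_residual_sd <- 0
  tc <- default_ground_truth("children")
  tc$noise$residual_sd <- 0; tc$noise$pupil_residual_sd <- 0
  co0 <- simulate_average_cohort(2L, ta, tc, seed = 5, fs = 250,
                                 channels = "Cz",
                                 between_subject_sd_scale = 0)
  kern <- rowSums(vapply(seq_len(nrow(ta$erp)), function(k)
    ta$erp$amp_novel_emotional[k] *
      topography_weights(ta$erp$electrode[k], ta$erp$spread[k])["Cz"] *
      erp_kernel(co0$time_eeg, ta$erp$latency_ms[k], ta$erp$width_ms[k]),
    numeric(length(co0$time_eeg))))
  expect_equal(as.numeric(co0$eeg[1, "novel_emotional", 1, ]), kern,
               tolerance = 1e-10)
})
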