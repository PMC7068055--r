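test_that("epoching matches the stated window arithmetic and baselines", {
  fs <- 500
  x <- matrix(rnorm(2 * 5000), 2, 5000,
              dimnames = list(c("Cz", "Fz"), NULL))
  ep <- epoch_and_baseline(x, c(500, 1500, 2500), fs)
  expect_equal(dim(ep$data), c(3, 2, 500))   # [-200, 800) ms at 500 Hz
  base_idx <- ep$time_ms >= -200 & ep$time_ms < 0
  for (i in 1:3)
    expect_equal(rowMeans(ep$data[i, , base_idx]), c(Cz = 0, Fz = 0),
                 tolerance = 1e-12)
  # constant channel -> zero after baselining
  xc <- matrix(5, 1, 3000, dimnames = list("Cz", NULL))
  epc <- epoch_and_baseline(xc, 1000, fs)
  expect_true(all(epc$data == 0))
  # boundary event dropped with reason
  epb <- epoch_and_baseline(x, c(1, 2500), fs)
  expect_false(epb$mask$included[1])
  expect_match(epb$mask$reason[1], "out of bounds")
  expect_true(epb$mask$included[2])
})

test_that("the 150 uV rule reads 'exceeding' strictly", {
  fs <- 500
  mk_epochs <- function(amp) {
    x <- matrix(0, 1, 3000, dimnames = list("Cz", NULL))
    x[1, 1200:1210] <- amp / 2
    x[1, 1220:1230] <- -amp / 2
    epoch_and_baseline(x, 1000, fs)
  }
  ok <- reject_amplitude_artifacts(mk_epochs(150))
  expect_true(ok$mask$included[1])          # range exactly 150: retained
  bad <- reject_amplitude_artifacts(mk_epochs(160))
  expect_false(bad$mask$included[1])        # -80..+80 -> range 160
  expect_match(bad$mask$reason[1], "amplitude")
  zero <- reject_amplitude_artifacts(epoch_and_baseline(
    matrix(0, 1, 3000, dimnames = list("Cz", NULL)), 1000, fs))
  expect_true(zero$mask$included[1])
})

test_that("standard-trial selection excludes lead-in and post-novel standards", {
  types <- c("standard", "standard", "novel_emotional", "standard",
             "standard", "standard", "novel_neutral", "standard",
             "standard")
  s <- data.frame(block_index = 1L, trial_index = seq_along(types),
                  trial_type = types)
  inc <- select_analysis_standards(s)
  expect_equal(which(inc), c(3L, 6L, 7L))   # novels + standard at 6
  # all-standard block: N - 2 retained
  s2 <- data.frame(block_index = 1L, trial_index = 1:10,
                   trial_type = rep("standard", 10))
  expect_equal(sum(select_analysis_standards(s2)), 8L)
  # default design: 224 - 2 - 2 * 56 standards retained unless post-novel
  # standards coincide with the lead-in (never: blocks open with standards)
  s3 <- generate_sound_sequence(seed = 9)
  inc3 <- select_analysis_standards(s3)
  retained_std <- sum(inc3 & s3$trial_type == "standard") / 4
  expect_equal(retained_std, 110)
  expect_true(all(inc3[s3$trial_type != "standard"]))
})

test_that("condition averaging is exact and accounts for every trial", {
  fs <- 500
  x <- matrix(rnorm(8000), 2, 4000, dimnames = list(c("Cz", "Fz"), NULL))
  onsets <- c(500, 1200, 1900, 2600)
  info <- data.frame(trial_type = c("standard", "standard",
                                    "novel_emotional", "novel_neutral"))
  ep <- epoch_and_baseline(x, onsets, fs, trial_info = info)
  av <- average_by_condition(ep)
  expect_equal(av$data["standard", , ],
               (ep$data[1, , ] + ep$data[2, , ]) / 2, tolerance = 1e-12)
  expect_equal(sort(rownames(av$data)),
               sort(c("standard", "novel_emotional", "novel_neutral")))
  expect_equal(unname(av$n_trials[c("standard", "novel_emotional")]),
               c(2L, 1L))
  # bookkeeping: retained + excluded = total, one reason per excluded trial
  ep2 <- epoch_and_baseline(x, c(1, onsets), fs,
                            trial_info = rbind(info[1, , drop = FALSE],
                                               info))
  ep2 <- reject_amplitude_artifacts(ep2)
  expect_equal(sum(ep2$mask$included) + sum(!ep2$mask$included),
               nrow(ep2$mask))
  expect_true(all(!is.na(ep2$mask$reason[!ep2$mask$included])))
  expect_true(all(is.na(ep2$mask$reason[ep2$mask$included])))
  # empty condition cell errors
  expect_error(average_by_condition(ep, include = c(FALSE, FALSE, TRUE,
                                                    TRUE)),
               "standard")
})

test_that("noiseless synthetic averages equal the generator truth through the chain", {
  cfg <- small_design(blocks = 1L, trials = 24L, novels = 3L)
  s <- generate_sound_sequence(cfg, seed = 2)
  sub <- synthesize_subject(s, default_ground_truth("adults"), seed = 1,
                            montage = small_montage(),
                            include_noise = FALSE, include_ocular = FALSE,
                            between_subject_sd_scale = 0)
  pre <- preprocess_subject_eeg(sub, run_ica = FALSE)
  av <- average_by_condition(pre$epochs, pre$include_design)
  tr <- sub$truth
  cz <- which(av$channels == "Cz")
  d <- av$data["novel_neutral", cz, ] - av$data["standard", cz, ]
  pred <- rowSums(vapply(seq_len(nrow(tr$erp)), function(k)
    (tr$erp$amp_novel_neutral[k] - tr$erp$amp_standard[k]) *
      topography_weights(tr$erp$electrode[k], tr$erp$spread[k],
                         small_montage())["Cz"] *
      erp_kernel(av$time_ms, tr$erp$latency_ms[k], tr$erp$width_ms[k]),
    numeric(length(av$time_ms))))
  expect_lt(max(abs(d - pred)) / max(abs(pred)), 0.01)
})
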