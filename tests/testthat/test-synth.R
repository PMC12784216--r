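test_that("the Weiss law has the right limits and solves the printed intensities", {
  expect_equal(weiss_threshold(7.1, 0.169, 1e9), 7.1, tolerance = 1e-6)
  for (b in c(2, 7.1)) for (cc in c(0.1, 0.8)) {
    expect_equal(weiss_threshold(b, cc, cc), 2 * b)
  }
  # rheobase/chronaxie solved from the two charge-form equations through
  # (9.5 mA, 0.5 ms) and (8.3 mA, 1 ms)
  expect_equal(weiss_threshold(7.1, 0.169, 0.5), 9.5, tolerance = 1e-3)
  expect_equal(weiss_threshold(7.1, 0.169, 1.0), 8.3, tolerance = 1e-3)
  expect_true(all(diff(weiss_threshold(7.1, 0.169, c(0.1, 0.3, 0.5, 1, 2))) < 0))
  expect_error(weiss_threshold(-1, 0.2, 1), "positive")
})

test_that("subject calibration hits the supplied thresholds and reports Weiss residuals", {
  s <- calibrate_subject(table1_intensities)
  expect_equal(unname(s$snap_threshold), unname(table1_intensities))
  expect_error(calibrate_subject(c("0.5" = 9.5)), "at least two")
  expect_error(calibrate_subject(c("0.5" = 8, "1" = 9)), "non-monotone")

  # least-squares Weiss fit vs grid-search oracle over (rheobase, chronaxie)
  pw <- c(0.1, 0.5, 1); ith <- unname(table1_intensities)
  ss <- function(b, cc) sum((b * (pw + cc) - ith * pw)^2)
  grid <- expand.grid(b = seq(5, 12, 0.01), cc = seq(0.05, 0.6, 0.005))
  best <- grid[which.min(mapply(ss, grid$b, grid$cc)), ]
  expect_equal(s$rheobase_snap, best$b, tolerance = 0.02)
  expect_equal(s$chronaxie_snap, best$cc, tolerance = 0.02)
  res <- attr(s, "weiss_residual_ma")
  expect_equal(length(res), 3)
  expect_gt(max(abs(res)), 1) # the 0.1 ms target is not Weiss-consistent

  # two-point calibration is exact, residuals ~ 0
  s2 <- calibrate_subject(c("0.5" = 9.5, "1" = 8.3))
  expect_equal(max(abs(attr(s2, "weiss_residual_ma"))), 0, tolerance = 1e-9)
})

test_that("cohort sampling is seed-stable and subject-k invariant to cohort size", {
  c6 <- sample_cohort(6, seed = 77)
  c12 <- sample_cohort(12, seed = 77)
  expect_equal(c6[[3]], c12[[3]])
  expect_equal(sample_cohort(5, seed = 77)[[2]], c6[[2]])
  expect_false(identical(c6[[1]]$snap_threshold, c6[[2]]$snap_threshold))
  cv <- sd(sapply(c12, function(s) s$snap_threshold[["1"]])) /
    mean(sapply(c12, function(s) s$snap_threshold[["1"]]))
  expect_equal(cv, 0.10, tolerance = 0.07)
  expect_equal(mean(sapply(c12, function(s) s$hand == "right")), 3 / 12)
})

test_that("recruitment is sigmoidal with the designed midpoint and floor", {
  s <- subject_params()
  thr <- fiber_threshold(s, 1, "snap")
  I50 <- thr + 2 * s$recruit_slope
  expect_equal(recruitment_amplitude(I50, 1, "snap", s), s$snap_max / 2)
  expect_lt(recruitment_amplitude(0, 1, "snap", s), 0.05 * s$snap_max)
  sweep <- recruitment_amplitude(seq(0, 30, by = 0.1), 1, "snap", s)
  expect_true(all(diff(sweep) >= 0))
  expect_error(recruitment_amplitude(-1, 1, "snap", s), ">= 0")
})

test_that("ISI trains honor the jitter bounds and the 0.5 Hz mean rate", {
  p0 <- stimulation_protocol(isi_jitter_frac = 0)
  expect_equal(diff(generate_isi_train(50, p0, seed = 1)), rep(2, 49))

  on <- generate_isi_train(10000, seed = 99)
  isi <- diff(c(0, on))
  expect_true(all(isi >= 1.8 & isi <= 2.2))
  rate <- 10000 / sum(isi)
  expect_equal(rate, 0.5, tolerance = 0.01 * 0.5)
  expect_identical(on, generate_isi_train(10000, seed = 99))
  expect_error(generate_isi_train(0), ">= 1")
})

test_that("EMG trial generation is deterministic and band-consistent", {
  s <- subject_params()
  a <- synth_emg_trial(10, 1, s, seed = 5)
  b <- synth_emg_trial(10, 1, s, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$snap, synth_emg_trial(10, 1, s, seed = 6)$snap))
  expect_length(a$snap, 320)
})

test_that("EEG sessions are reproducible and internally consistent", {
  s <- subject_params()
  proto <- stimulation_protocol(n_trials = 15, seed = 3)
  ses1 <- synth_eeg_session(s, proto, 0.5, seed = 3)
  ses2 <- synth_eeg_session(s, proto, 0.5, seed = 3)
  expect_identical(ses1$eeg$data, ses2$eeg$data)
  expect_identical(ses1$truth, ses2$truth)

  # conservation: one truth record per event per trial
  expect_equal(nrow(ses1$truth), 15)
  expect_equal(length(ses1$eeg$events), 15)
  expect_true(all(diff(ses1$eeg$events) > 0))
  expect_error(synth_eeg_session(s, proto, 0.3, seed = 3), "not among")
})

test_that("noiseless sessions place the configured components exactly", {
  s <- subject_params()
  proto <- stimulation_protocol(n_trials = 5, seed = 4)
  for (pw in c("0.5", "1")) {
    ses <- synth_eeg_session(s, proto, as.numeric(pw), seed = 4, noise = FALSE)
    ep <- epoch_and_baseline(ses$eeg)
    ch <- match(ses$target_channel, ep$labels)
    avg <- apply(ep$data[, ch, , drop = FALSE], 3, mean)
    # peaks equal the configured amplitudes up to component-overlap tails
    expect_equal(max(avg), unname(s$p50_amp[pw]), tolerance = 0.02)
    expect_equal(min(avg), unname(s$n70_amp[pw]), tolerance = 0.02)
  }
})

test_that("the default calibration orders N70 magnitude across pulse widths", {
  s <- subject_params()
  proto <- stimulation_protocol(n_trials = 25, seed = 11)
  n70 <- vapply(c(0.1, 0.5, 1), function(pw) {
    ses <- synth_eeg_session(s, proto, pw, seed = 11)
    ep <- epoch_and_baseline(laplacian_montage(preprocess_eeg(ses$eeg)))
    average_sep(ep, ses$target_channel)$peaks$amplitude[2]
  }, numeric(1))
  expect_true(all(diff(abs(n70)) > 0)) # |N70(0.1)| < |N70(0.5)| < |N70(1)|
  expect_true(all(n70 < 0))
})

test_that("generated EEG background has decreasing spectral power over 2-40 Hz", {
  s <- subject_params()
  proto <- stimulation_protocol(n_trials = 10, seed = 13)
  ses <- synth_eeg_session(s, proto, 1, seed = 13)
  fs <- ses$eeg$fs
  slopes <- apply(ses$eeg$data[1:5, ], 1, function(v) {
    sp <- stats::spec.pgram(stats::ts(v, frequency = fs), spans = 21, plot = FALSE)
    keep <- sp$freq >= 2 & sp$freq <= 40 & (sp$freq < 9 | sp$freq > 11) # skip alpha peak
    coef(stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2]
  })
  expect_true(all(slopes < 0))
  # low-frequency band power exceeds high-frequency band power
  sp <- stats::spec.pgram(stats::ts(ses$eeg$data[1, ], frequency = fs),
                          spans = 21, plot = FALSE)
  expect_gt(mean(sp$spec[sp$freq >= 3 & sp$freq <= 8]),
            mean(sp$spec[sp$freq >= 25 & sp$freq <= 40]))
})

test_that("artifact trials are injected at the requested fraction", {
  s <- subject_params()
  proto <- stimulation_protocol(n_trials = 40, seed = 17)
  ses <- synth_eeg_session(s, proto, 1, seed = 17, artifact_fraction = 0.25)
  frac <- mean(ses$truth$artifact)
  expect_gt(frac, 0.05); expect_lt(frac, 0.5)
  # artifact trials are flagged by the averaged-SEP trial rejection
  ep <- epoch_and_baseline(preprocess_eeg(ses$eeg))
  masked <- reject_bad_trials(ep, "C4")
  expect_gt(sum(!masked$mask[ses$truth$artifact]), 0)
})
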