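test_that("charge is the exact pulse-width x current product", {
  expect_equal(compute_charge(8.3, 1), 8.30e-06)
  expect_equal(compute_charge(9.5, 0.5), 4.75e-06)
  expect_equal(compute_charge(0, 123), 0)
  # bilinear: doubling either factor doubles the charge
  expect_equal(compute_charge(2 * 8.3, 1), 2 * compute_charge(8.3, 1))
  expect_equal(compute_charge(8.3, 2), 2 * compute_charge(8.3, 1))
  expect_error(compute_charge(-1, 1), "non-negative")
})

test_that("EMG band-pass rejects DC and line noise but passes the SNAP band", {
  fs <- 3200
  const <- filter_emg(rep(5, 2000), fs)
  expect_lt(max(abs(const)), 5e-6)
  g200 <- sine_gain(function(v) filter_emg(v, fs), 200, fs)
  expect_gt(g200, 0.95)
  expect_lt(g200, 1.05)
  g60 <- sine_gain(function(v) filter_emg(v, fs), 60, fs)
  expect_lt(20 * log10(g60), -20)
  expect_error(filter_emg(rnorm(100), fs = 600), "too low")
})

test_that("background level matches the rectified-median definition", {
  # 320-sample epoch grid; place known values in the [-50, -15) window
  tr <- numeric(320)
  idx <- window_index(c(-50, -15), 3200, -50)
  tr[idx] <- rep(c(-1, 2, -3), length.out = length(idx))
  ep <- make_emg_trial(tr)
  bg <- background_level(ep)
  expect_equal(bg$median, 2)

  zeros <- emg_epochs(matrix(0, 4, 320))
  expect_equal(background_level(zeros), list(median = 0, sd = 0))

  set.seed(3)
  noisy <- emg_epochs(matrix(rnorm(200 * 320, sd = 2.5), 200, 320))
  bgn <- background_level(noisy)
  expect_equal(bgn$median, 0.674 * 2.5, tolerance = 0.05)
  expect_error(background_level(ep, window = c(-80, -60)), "outside")
})

test_that("peak response returns signed peaks with earliest-tie latency", {
  flat <- make_emg_trial(numeric(320))
  pk <- peak_response(flat, c(2, 8))
  expect_equal(pk$amplitude, 0)
  expect_equal(pk$latency_ms, 1.875) # window start under the floor convention

  # two equal peaks at 3 and 6 ms: earliest wins
  tr <- numeric(320)
  t <- emg_grid_times()
  tr[which.min(abs(t - 3))] <- 7
  tr[which.min(abs(t - 6))] <- 7
  pk2 <- peak_response(make_emg_trial(tr), c(2, 8))
  expect_equal(pk2$amplitude, 7)
  expect_equal(pk2$latency_ms, 3.125)

  # polarity options
  tr[which.min(abs(t - 5))] <- -9
  expect_equal(peak_response(make_emg_trial(tr), c(2, 8), "min")$amplitude, -9)
  expect_equal(peak_response(make_emg_trial(tr), c(2, 8), "absmax")$amplitude, -9)
  expect_error(peak_response(flat, c(40, 60)), "outside")
})

test_that("noiseless SNAP trials reproduce the generator truth exactly", {
  subj <- subject_params()
  tr <- synth_emg_trial(12, 1, subj, noise = FALSE)
  ep <- make_emg_trial(tr$snap)
  pk <- peak_response(ep, c(2, 8))
  expect_equal(pk$amplitude, tr$truth$snap_amp)
  expect_equal(pk$latency_ms, tr$truth$snap_lat)
  expect_equal(pk$latency_ms, 3.75) # 3.8 ms snapped to the 3200 Hz grid
  ck <- peak_response(make_emg_trial(tr$cmap), c(3, 15))
  expect_equal(ck$amplitude, tr$truth$cmap_amp)
  expect_equal(ck$latency_ms, tr$truth$cmap_lat)

  # saturation: far above I50 the SNAP peak equals snap_max
  sat <- synth_emg_trial(40, 1, subj, noise = FALSE)
  expect_equal(peak_response(make_emg_trial(sat$snap), c(2, 8))$amplitude,
               subj$snap_max, tolerance = 1e-6)

  # no stimulus: nothing above the (zero) background in the SNAP window
  rest <- synth_emg_trial(0, 1, subj, noise = FALSE)
  expect_lt(peak_response(make_emg_trial(rest$snap), c(2, 8))$amplitude, 1e-6)
})

test_that("recruitment curves average groups of four and ignore trial order", {
  subj <- subject_params()
  levels <- seq(6, 12, by = 0.5)
  ses <- synth_recruitment_session(subj, 1, intensities = levels, noise = FALSE)
  curve <- build_recruitment_curve(ses$snap)
  expect_equal(curve$intensities, levels)
  expect_equal(curve$n_per_level, rep(4L, length(levels)))
  expect_equal(curve$mean,
               recruitment_amplitude(levels, 1, "snap", subj))

  # shuffling trials leaves the curve unchanged
  perm <- sample(nrow(ses$snap$data))
  shuffled <- emg_epochs(ses$snap$data[perm, ], intensity = ses$snap$intensity[perm])
  expect_equal(build_recruitment_curve(shuffled)$mean, curve$mean)

  one <- emg_epochs(matrix(rnorm(4 * 320), 4, 320), intensity = rep(5, 4))
  expect_error(build_recruitment_curve(one), "2 intensity levels")
})

test_that("the target-intensity rule follows the 3-of-4, 3-SD criterion", {
  # all-noise curve: no level qualifies
  noise_curve <- make_curve(c(5, 5.5, 6),
                            list(rnorm(4, 0, 0.1), rnorm(4, 0, 0.1), rnorm(4, 0, 0.1)),
                            bg_median = 0, bg_sd = 1)
  expect_true(is.na(detect_target_intensity(noise_curve)))

  # exactly 3/4 supra-criterion at level k, 2/4 at k-1 -> level k
  crit <- 0 + 3 * 1
  boundary <- make_curve(c(5, 5.5, 6),
                         list(c(4, 4, 1, 1), c(4, 4, 4, 1), c(4, 4, 4, 4)),
                         bg_median = 0, bg_sd = 1)
  expect_equal(detect_target_intensity(boundary), 5.5)

  # monotonicity: raising all SNAP amplitudes never increases the target
  raised <- make_curve(c(5, 5.5, 6),
                       list(c(4, 4, 1, 1) + 3, c(4, 4, 4, 1) + 3, c(4, 4, 4, 4) + 3),
                       bg_median = 0, bg_sd = 1)
  expect_lte(detect_target_intensity(raised), detect_target_intensity(boundary))

  # joint rule: CMAP must also be discernable at the level
  cmap_late <- make_curve(c(5, 5.5, 6),
                          list(c(0, 0, 0, 0), c(0, 0, 0, 0), c(9, 9, 9, 9)),
                          bg_median = 0, bg_sd = 1)
  expect_equal(detect_target_intensity(boundary, cmap_late), 6)
})

test_that("detected targets track the calibrated thresholds on synthetic cohorts", {
  errs <- c()
  for (k in 1:3) {
    subj <- calibrate_subject(table1_intensities, seed = derive_seed(42, 1, k))
    for (pw in c(0.5, 1)) {
      ses <- synth_recruitment_session(subj, pw, seed = derive_seed(42, 2, k, round(pw * 10)))
      sc <- build_recruitment_curve(filter_emg(ses$snap), c(2, 8))
      cc <- build_recruitment_curve(filter_emg(ses$cmap), c(3, 15))
      target <- detect_target_intensity(sc, cc)
      errs <- c(errs, target - fiber_threshold(subj, pw, "snap"))
    }
  }
  # within one 0.5 mA recruitment step of the (off-grid) calibrated threshold
  expect_true(all(abs(errs) <= 0.75))
})

test_that("the maintenance controller holds the CMAP band with 0.1 mA steps", {
  # all trials in band: no adjustment
  quiet <- data.frame(snap = rnorm(20, 10, 0.1), cmap = rnorm(20, 400, 5))
  log <- monitor_assessment(quiet, start_intensity = 9,
                            target_snap = 10, target_cmap = 400)
  expect_equal(sum(log$adjustment != 0), 0)
  expect_true(all(log$in_band))

  # alternating +/-15 percent stays within the 20 percent band
  alt <- data.frame(snap = rep(10, 20), cmap = 400 * (1 + rep(c(0.15, -0.15), 10)))
  expect_equal(sum(monitor_assessment(alt, start_intensity = 9, target_snap = 10,
                                      target_cmap = 400)$adjustment != 0), 0)

  # sustained 30 percent sag: upward 0.1 mA steps until back in band
  subj <- subject_params()
  target <- fiber_threshold(subj, 1, "snap") + 0.5
  obs <- synth_assessment_observer(subj, 1, seed = 3, drift = 0.7, noise = FALSE)
  base <- obs(target, 1)
  log2 <- monitor_assessment(obs, n_trials = 40, start_intensity = target,
                             target_snap = base[["snap"]] / 0.7,
                             target_cmap = base[["cmap"]] / 0.7)
  expect_true(all(log2$adjustment %in% c(0, 0.1)))
  expect_gt(sum(log2$adjustment == 0.1), 0)
  expect_true(all(tail(log2$in_band, 10))) # steady state back in band
  expect_true(all(diff(log2$intensity) >= 0))

  # delivered intensity is capped by the discomfort limit
  sag <- data.frame(snap = rep(1, 30), cmap = rep(100, 30))
  capped <- monitor_assessment(sag, start_intensity = 9.95, target_snap = 10,
                               target_cmap = 400, discomfort_limit = 10.05)
  expect_true(all(capped$intensity <= 10.05))
})

test_that("emg_epochs validates its geometry", {
  expect_error(emg_epochs(matrix(0, 2, 100)), "expected 320 samples")
  expect_error(emg_epochs(matrix(0, 2, 320), intensity = 1:3), "one value per trial")
})
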