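test_that("recordings validate labels and events", {
  expect_error(eeg_recording(matrix(0, 2, 10), labels = c("C3", "C3")), "unique")
  expect_error(eeg_recording(matrix(0, 2, 10), labels = c("C3", "C4"),
                             events = c(5, 20)), "outside")
  expect_error(eeg_recording(matrix(0, 2, 10), labels = c("C3", "C4"),
                             events = c(5, 5)), "strictly increasing")
})

test_that("bad channels are rejected by robust amplitude, protecting C3/C4", {
  set.seed(12)
  rec <- make_flat_recording()
  rec$data <- matrix(rnorm(19 * 3000), 19, 3000)
  clean <- reject_bad_channels(rec)
  expect_length(attr(clean, "rejected"), 0)

  noisy <- rec
  i <- match("O1", noisy$labels)
  noisy$data[i, ] <- rnorm(3000, sd = 10)
  expect_equal(attr(reject_bad_channels(noisy), "rejected"), "O1")

  flat <- rec
  flat$data[match("Fp2", flat$labels), ] <- 3.14
  expect_equal(attr(reject_bad_channels(flat), "rejected"), "Fp2")

  lost <- rec
  lost$data[match("C4", lost$labels), ] <- rnorm(3000, sd = 10)
  expect_error(reject_bad_channels(lost), "analysis channel")
})

test_that("EEG preprocessing notches line noise, removes DC, passes 10 Hz", {
  fs <- 300
  pp <- function(v) {
    rec <- eeg_recording(rbind(v, v), fs, c("C3", "C4"))
    preprocess_eeg(rec)$data[1, ]
  }
  g60 <- sine_gain(pp, 60, fs, dur_s = 20)
  expect_lt(20 * log10(g60), -30)
  g10 <- sine_gain(pp, 10, fs, dur_s = 20)
  expect_gt(g10, 0.95); expect_lt(g10, 1.05)
  dc <- pp(rep(4, 3000))
  expect_lt(max(abs(dc[500:2500])), 1e-6)
  expect_error(preprocess_eeg(eeg_recording(matrix(0, 2, 100), 100, c("C3", "C4"))),
               "Nyquist")
})

test_that("filtering is linear to numerical precision", {
  set.seed(13)
  x <- rnorm(2000); y <- rnorm(2000)
  rec_of <- function(v) eeg_recording(rbind(v, v), 300, c("C3", "C4"))
  f <- function(v) preprocess_eeg(rec_of(v))$data[1, ]
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-9)
})

test_that("the Hjorth Laplacian subtracts the neighbor mean", {
  rec <- make_flat_recording(n_samp = 100)
  rec$data[] <- 2.5 # spatially constant montage
  for (ch in c("C3", "C4", "P4", "Cz")) {
    expect_equal(laplacian(rec, ch), rep(0, 100))
  }

  rec2 <- make_flat_recording(n_samp = 10)
  rec2$data[match("C4", rec2$labels), ] <- 5
  rec2$data[match(c("F4", "P4", "Cz", "T8"), rec2$labels), ] <- 1
  expect_equal(laplacian(rec2, "C4"), rep(4, 10))

  # missing neighbor: mean over the remaining three
  keep <- setdiff(montage_1020, "T8")
  rec3 <- eeg_recording(rec2$data[match(keep, rec2$labels), ], 300, keep)
  expect_equal(laplacian(rec3, "C4"), rep(5 - 1, 10))

  two <- eeg_recording(matrix(0, 2, 10), 300, c("C4", "F4"))
  expect_error(laplacian(two, "C4"), "fewer than 2")
})

test_that("epoching drops edge events and zeroes the baseline", {
  set.seed(14)
  rec <- make_flat_recording(n_samp = 2000)
  rec$data <- matrix(rnorm(19 * 2000), 19, 2000)
  rec$events <- c(5L, 300L, 600L, 1990L) # first and last too close to edges
  ep <- epoch_and_baseline(rec)
  expect_equal(dim(ep$data)[1], 2)
  expect_equal(attr(ep, "dropped_events"), c(1L, 4L))
  bidx <- window_index(c(-50, 0), 300, -50)
  expect_equal(max(abs(apply(ep$data[, , bidx], c(1, 2), mean))), 0, tolerance = 1e-12)

  const <- make_flat_recording(n_samp = 1000)
  const$data[] <- 7; const$events <- c(300L, 600L)
  epc <- epoch_and_baseline(const)
  expect_equal(max(abs(epc$data)), 0)
})

test_that("bad-trial masking catches artifacts without over-masking", {
  set.seed(15)
  subj <- subject_params()
  ses <- synth_eeg_session(subj, stimulation_protocol(n_trials = 40, seed = 2),
                           pulse_width = 1, seed = 2)
  ep <- epoch_and_baseline(preprocess_eeg(ses$eeg))
  masked <- reject_bad_trials(ep, "C4")
  expect_lte(mean(!masked$mask), 0.05) # false-alarm bound on homogeneous trials

  spiked <- ep
  spiked$data[7, match("C4", ep$labels), ] <-
    spiked$data[7, match("C4", ep$labels), ] + 50 * sd(ep$data)
  expect_false(reject_bad_trials(spiked, "C4")$mask[7])

  small <- ep; small$data <- ep$data[1:9, , , drop = FALSE]; small$mask <- rep(TRUE, 9)
  expect_error(reject_bad_trials(small, "C4"), "at least 10")
})

test_that("averaged SEP recovers noiseless generator truth exactly", {
  subj <- subject_params()
  for (pw in c(0.1, 1)) {
    ses <- synth_eeg_session(subj, stimulation_protocol(n_trials = 8, seed = 4),
                             pulse_width = pw, seed = 4, noise = FALSE)
    ep <- epoch_and_baseline(ses$eeg) # raw channel, no spatial/temporal filtering
    sep <- average_sep(ep, ses$target_channel)
    expect_equal(sep$peaks$amplitude[1], ses$truth$p50_peak_clean[1], tolerance = 1e-9)
    expect_equal(sep$peaks$amplitude[2], ses$truth$n70_peak_clean[1], tolerance = 1e-9)
    expect_equal(sep$peaks$latency_ms[1], ses$truth$p50_lat[1])
    expect_equal(sep$peaks$latency_ms[2], ses$truth$n70_lat[1])
    expect_lte(sep$peaks$amplitude[2], 0) # N70 sign contract
  }
})

test_that("averaged SEP commutes with trial permutation and respects the mask", {
  set.seed(16)
  subj <- subject_params()
  ses <- synth_eeg_session(subj, stimulation_protocol(n_trials = 20, seed = 6),
                           pulse_width = 0.5, seed = 6)
  ep <- epoch_and_baseline(preprocess_eeg(ses$eeg))
  sep1 <- average_sep(ep, "C4")
  perm <- sample(20)
  ep2 <- ep; ep2$data <- ep$data[perm, , ]; ep2$mask <- ep$mask[perm]
  expect_equal(average_sep(ep2, "C4")$trace, sep1$trace)

  none <- ep; none$mask[] <- FALSE
  expect_error(average_sep(none, "C4"), "no unmasked")
})

test_that("r-squared topography separates labels and peaks at the target channel", {
  # hand-built epochs: channel 1 separates perfectly, channel 2 not at all
  arr <- array(0, c(4, 2, 105))
  arr[, 1, 40:51] <- c(10, 10, 10, 10) # component >> background on ch 1
  arr[, 2, 40:51] <- c(1, 0, 1, 0)
  arr[, 2, 1:15] <- c(1, 0, 1, 0) # identical distribution in background
  ep <- structure(list(data = arr, fs = 300, window = c(-50, 300),
                       baseline = c(-50, 0), labels = c("A", "B"),
                       mask = rep(TRUE, 4)), class = "eeg_epochs")
  topo <- topography_r2(ep, c(80, 120))
  expect_equal(topo$r2[1], 1)
  expect_equal(topo$r2[2], 0)
  expect_true(all(topo$r2 >= 0 & topo$r2 <= 1))

  # group-level map: the contralateral central channel carries the max N70 r2
  coh <- sample_cohort(8, seed = 1, hand = "left")
  maps <- sapply(seq_along(coh), function(k) {
    ses <- synth_eeg_session(coh[[k]], stimulation_protocol(n_trials = 40, seed = k),
                             pulse_width = 1, seed = derive_seed(1, 20, k))
    ep <- epoch_and_baseline(laplacian_montage(preprocess_eeg(ses$eeg)),
                             baseline = NULL)
    topography_r2(ep, c(55, 95), component_tag = "N70")$r2
  })
  avg <- rowMeans(maps)
  expect_equal(montage_1020[which.max(avg)], "C4")
})

test_that("the impaired profile moves the N70 to parietal sites and shrinks it", {
  subj <- subject_params(impaired = TRUE)
  ses <- synth_eeg_session(subj, stimulation_protocol(n_trials = 70, seed = 9),
                           pulse_width = 1, seed = 9)
  expect_equal(ses$n70_channel, "P4")
  ep <- epoch_and_baseline(laplacian_montage(preprocess_eeg(ses$eeg)))
  # averaged SEP: N70 prominent at P4, no comparable negativity at C4
  sep_p4 <- average_sep(ep, "P4")
  sep_c4 <- average_sep(ep, "C4")
  expect_lt(sep_p4$peaks$amplitude[2], sep_c4$peaks$amplitude[2])
  # and smaller in magnitude than the healthy N70 at the central channel
  healthy <- subject_params()
  ses_h <- synth_eeg_session(healthy, stimulation_protocol(n_trials = 70, seed = 9),
                             pulse_width = 1, seed = 9)
  ep_h <- epoch_and_baseline(laplacian_montage(preprocess_eeg(ses_h$eeg)))
  expect_lt(abs(average_sep(ep, "P4")$peaks$amplitude[2]),
            abs(average_sep(ep_h, "C4")$peaks$amplitude[2]))
})
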