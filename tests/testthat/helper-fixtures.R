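# Shared fixtures, built in code at test time.

table1_intensities <- c("0.1" = 24.2, "0.5" = 9.5, "1" = 8.3)

# small sinusoid-friendly recording: n channels of zeros with events
make_flat_recording <- function(n_ch = 19, n_samp = 3000, fs = 300,
                                labels = montage_1020[seq_len(n_ch)],
                                events = integer()) {
  eeg_recording(matrix(0, n_ch, n_samp), fs, labels, events)
}

# emg_epochs whose single trial is an arbitrary trace on the [-50, 50) grid
make_emg_trial <- function(trace, fs = 3200) {
  emg_epochs(matrix(trace, 1), fs = fs, window = c(-50, 50))
}

emg_grid_times <- function(fs = 3200) epoch_times(320, fs, -50)

# hand-rolled recruitment curve object for rule-boundary tests
make_curve <- function(intensities, amps_by_level, bg_median = 0, bg_sd = 1) {
  trials <- do.call(rbind, lapply(seq_along(intensities), function(i) {
    data.frame(amplitude = amps_by_level[[i]], intensity = intensities[i])
  }))
  structure(list(intensities = intensities,
                 mean = vapply(amps_by_level, mean, numeric(1)),
                 n_per_level = vapply(amps_by_level, length, integer(1)),
                 trials = trials,
                 background = list(median = bg_median, sd = bg_sd),
                 window = c(2, 8), target_intensity = NA_real_),
            class = "recruitment_curve")
}

# brute-force ROC AUC over all pairs (independent oracle)
auc_bruteforce <- function(comp, bg) {
  s <- 0
  for (a in comp) for (b in bg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(comp) * length(bg))
}

# steady-state sinusoid gain through a filtering function, measured on the
# central half of a long record to avoid edge transients
sine_gain <- function(filter_fun, freq, fs, dur_s = 10) {
  t <- seq(0, dur_s, by = 1 / fs)
  y <- filter_fun(sin(2 * pi * freq * t))
  mid <- y[round(length(y) * 0.25):round(length(y) * 0.75)]
  max(abs(mid))
}
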