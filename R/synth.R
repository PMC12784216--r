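# Seeded generator of synthetic stimulation sessions: strength-duration
# (rheobase/chronaxie) thresholds, sigmoidal SNAP/CMAP recruitment, jittered
# stimulus trains, per-trial EMG traces, and 19-channel EEG with embedded
# P50/N70 components over a 1/f + alpha + line-noise background. Every
# stochastic element is driven by explicit seeds with fixed splitting, so a
# subject's data are invariant to cohort size.

# Gaussian-windowed cosine kernel; unit peak at t0 (ms), f in Hz.
gausscos <- function(t_ms, t0, sigma_ms, f_hz) {
  exp(-(t_ms - t0)^2 / (2 * sigma_ms^2)) * cos(2 * pi * f_hz * (t_ms - t0) / 1000)
}

# Default calibration targets: group-mean target intensities (mA) and P50/N70
# component amplitudes (a.u.) / latencies (ms) per pulse-width condition.
default_target_intensities <- c("0.1" = 24.2, "0.5" = 9.5, "1" = 8.3)
default_p50_amp <- c("0.1" = 46.4, "0.5" = 49.3, "1" = 55.4)
default_n70_amp <- c("0.1" = -39.0, "0.5" = -55.1, "1" = -66.9)

#' Strength-duration (Weiss) threshold
#'
#' Threshold current for a rectangular pulse from the Weiss strength-duration
#' law: `rheobase * (1 + chronaxie / pulse_width)`. Strictly decreasing in
#' pulse width and tending to the rheobase for long pulses.
#'
#' @param rheobase Rheobase current in mA (> 0).
#' @param chronaxie Chronaxie in ms (> 0).
#' @param pulse_width Pulse width in ms (> 0), vectorized.
#' @return Threshold current in mA.
#' @examples
#' weiss_threshold(7.1, 0.169, c(0.5, 1)) # ~9.5, ~8.3 mA
#' @export
weiss_threshold <- function(rheobase, chronaxie, pulse_width) {
  stop_if_not_positive(rheobase = rheobase, chronaxie = chronaxie,
                       pulse_width = pulse_width)
  rheobase * (1 + chronaxie / pulse_width)
}

#' Synthetic subject parameters
#'
#' Bundle of generator parameters describing one simulated participant. The
#' defaults are calibrated to the group means of the study conditions this
#' package emulates: detectable-SNAP target intensities of 24.2 / 9.5 / 8.3 mA
#' at 0.1 / 0.5 / 1 ms pulse widths, P50/N70 amplitudes per condition, and
#' P50/N70 latencies of 44.2 / 80.6 ms.
#'
#' @param snap_threshold Named vector of detectable-SNAP threshold intensities
#'   (mA) per pulse width (names in ms).
#' @param cmap_threshold Same for the CMAP; defaults to 0.5 mA below the SNAP
#'   thresholds so a small but discernable CMAP accompanies the target SNAP.
#' @param rheobase_snap,chronaxie_snap,rheobase_cmap,chronaxie_cmap
#'   Strength-duration parameters (mA, ms) used to interpolate thresholds at
#'   uncalibrated pulse widths.
#' @param recruit_slope Sigmoid scale of the recruitment curve (mA).
#' @param snap_max,cmap_max Saturated response amplitudes (a.u.).
#' @param p50_amp,n70_amp Named per-pulse-width component amplitudes (a.u.;
#'   N70 negative).
#' @param p50_lat,n70_lat Component latencies (ms).
#' @param lat_jitter_sd Trial-to-trial latency jitter SD (ms).
#' @param amp_cv Trial-to-trial amplitude coefficient of variation.
#' @param emg_noise_sd,eeg_noise_sd Background noise SDs (a.u.).
#' @param discomfort_limit Maximum tolerated intensity (mA); must exceed the
#'   threshold at every calibrated pulse width.
#' @param hand Stimulated hand, `"left"` (analyzed at C4) or `"right"` (C3).
#' @param impaired Logical; if TRUE the N70 is reduced and shifted posteriorly
#'   (parietal P4/P3), emulating an impaired afferent profile.
#' @return A `subject_params` object.
#' @export
subject_params <- function(snap_threshold = default_target_intensities,
                           cmap_threshold = snap_threshold - 0.5,
                           rheobase_snap = 7.1, chronaxie_snap = 0.169,
                           rheobase_cmap = 6.6, chronaxie_cmap = 0.169,
                           recruit_slope = 0.5,
                           snap_max = 100, cmap_max = 1500,
                           p50_amp = default_p50_amp,
                           n70_amp = default_n70_amp,
                           p50_lat = 44.2, n70_lat = 80.6,
                           lat_jitter_sd = 3, amp_cv = 0.10,
                           emg_noise_sd = 5, eeg_noise_sd = 45,
                           discomfort_limit = 45,
                           hand = "left", impaired = FALSE) {
  stop_if_not_positive(rheobase_snap = rheobase_snap, chronaxie_snap = chronaxie_snap,
                       rheobase_cmap = rheobase_cmap, chronaxie_cmap = chronaxie_cmap,
                       recruit_slope = recruit_slope, snap_max = snap_max,
                       cmap_max = cmap_max, p50_lat = p50_lat, n70_lat = n70_lat,
                       lat_jitter_sd = lat_jitter_sd, amp_cv = amp_cv,
                       emg_noise_sd = emg_noise_sd, eeg_noise_sd = eeg_noise_sd,
                       discomfort_limit = discomfort_limit)
  if (p50_lat >= n70_lat) stop("p50_lat must precede n70_lat", call. = FALSE)
  if (any(p50_amp <= 0)) stop("p50_amp must be positive", call. = FALSE)
  if (any(n70_amp >= 0)) stop("n70_amp must be negative", call. = FALSE)
  if (is.null(names(snap_threshold))) stop("snap_threshold must be named by pulse width", call. = FALSE)
  if (any(discomfort_limit <= snap_threshold)) {
    stop("discomfort_limit must exceed the threshold at every pulse width", call. = FALSE)
  }
  hand <- match.arg(hand, c("left", "right"))
  structure(list(snap_threshold = snap_threshold, cmap_threshold = cmap_threshold,
                 rheobase_snap = rheobase_snap, chronaxie_snap = chronaxie_snap,
                 rheobase_cmap = rheobase_cmap, chronaxie_cmap = chronaxie_cmap,
                 recruit_slope = recruit_slope, snap_max = snap_max,
                 cmap_max = cmap_max, p50_amp = p50_amp, n70_amp = n70_amp,
                 p50_lat = p50_lat, n70_lat = n70_lat,
                 lat_jitter_sd = lat_jitter_sd, amp_cv = amp_cv,
                 emg_noise_sd = emg_noise_sd, eeg_noise_sd = eeg_noise_sd,
                 discomfort_limit = discomfort_limit, hand = hand,
                 impaired = impaired),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("Synthetic subject (%s hand%s): thresholds [%s] mA at [%s] ms\n",
              x$hand, if (x$impaired) ", impaired profile" else "",
              paste(round(x$snap_threshold, 1), collapse = ", "),
              paste(names(x$snap_threshold), collapse = ", ")))
  invisible(x)
}

#' Contralateral central analysis channel for a stimulated hand
#' @param hand `"left"` or `"right"`.
#' @return `"C4"` for left-hand stimulation, `"C3"` for right.
#' @export
contralateral_channel <- function(hand) {
  switch(match.arg(hand, c("left", "right")), left = "C4", right = "C3")
}

#' Calibrate a synthetic subject to mean target intensities
#'
#' Builds a [subject_params] whose detectable-SNAP threshold sits at the
#' supplied intensity for each pulse width. A Weiss strength-duration law is
#' fitted by least squares in the linear charge form (`Q = b (t + c)`, i.e.
#' charge regressed on pulse width) and kept for interpolation, but because
#' empirical targets need not be exactly Weiss-consistent the per-pulse-width
#' thresholds are stored directly and the Weiss residual at each calibrated
#' pulse width is reported in attribute `"weiss_residual_ma"` rather than
#' hidden.
#'
#' @param mean_intensities Named numeric vector, `pulse width (ms) -> mA`,
#'   at least two pairs; thresholds must decrease with pulse width.
#' @param seed Optional integer seed for population sampling.
#' @param cv Between-subject coefficient of variation applied multiplicatively
#'   to thresholds and component amplitudes when `seed` is given (default 0.10
#'   matches the across-participant dispersion of the calibration targets).
#' @param ... Further arguments passed to [subject_params()].
#' @return A `subject_params` object.
#' @export
calibrate_subject <- function(mean_intensities, seed = NULL, cv = 0.10, ...) {
  if (length(mean_intensities) < 2) {
    stop("need at least two (pulse width, intensity) pairs", call. = FALSE)
  }
  if (is.null(names(mean_intensities))) {
    stop("mean_intensities must be named by pulse width (ms)", call. = FALSE)
  }
  pw <- as.numeric(names(mean_intensities))
  ord <- order(pw)
  pw <- pw[ord]; ith <- as.numeric(mean_intensities)[ord]
  if (any(diff(ith) >= 0)) {
    stop("thresholds must decrease with pulse width (non-monotone pairs)", call. = FALSE)
  }
  # linear charge form: Q = I * t = b * t + b * c
  fit <- stats::lm(q ~ pw, data = data.frame(q = ith * pw, pw = pw))
  b <- unname(stats::coef(fit)[2]); bc <- unname(stats::coef(fit)[1])
  if (b <= 0 || bc <= 0) stop("calibration error: inconsistent pairs", call. = FALSE)
  chron <- bc / b
  thr <- stats::setNames(ith, names(mean_intensities)[ord])
  scale_thr <- 1; scale_amp <- 1
  if (!is.null(seed) && cv > 0) {
    z <- with_seed(seed, stats::rnorm(2))
    scale_thr <- max(0.5, 1 + cv * z[1])
    scale_amp <- max(0.5, 1 + cv * z[2])
  }
  dots <- list(...)
  amp_args <- list(p50_amp = default_p50_amp * scale_amp,
                   n70_amp = default_n70_amp * scale_amp)
  amp_args <- utils::modifyList(amp_args, dots[intersect(names(dots), names(amp_args))])
  dots <- dots[setdiff(names(dots), names(amp_args))]
  sp <- do.call(subject_params,
                c(list(snap_threshold = thr * scale_thr,
                       rheobase_snap = b, chronaxie_snap = chron,
                       rheobase_cmap = max(b - 0.5, 0.1), chronaxie_cmap = chron),
                  amp_args, dots))
  attr(sp, "weiss_residual_ma") <-
    stats::setNames(weiss_threshold(b, chron, pw) - ith, names(thr))
  sp
}

#' Sample a synthetic cohort
#'
#' Draws `n` subjects around the default calibration (between-subject CV 0.10
#' on thresholds and component amplitudes). Hands are assigned 3 right-hand
#' stimulations per 12 subjects (the rest left), mirroring the emulated study
#' composition. Subject k's parameters depend only on `(seed, k)`.
#'
#' @param n Cohort size.
#' @param seed Master integer seed.
#' @param mean_intensities Calibration targets passed to [calibrate_subject()].
#' @param hand Optional fixed stimulated hand for the whole cohort; by default
#'   every fourth subject is stimulated on the right hand.
#' @param ... Further arguments forwarded to [subject_params()].
#' @return List of `subject_params`.
#' @export
sample_cohort <- function(n, seed, mean_intensities = default_target_intensities,
                          hand = NULL, ...) {
  lapply(seq_len(n), function(k) {
    hand_k <- if (is.null(hand)) {
      if (k %% 4 == 0) "right" else "left"
    } else hand
    calibrate_subject(mean_intensities, seed = derive_seed(seed, 1L, k),
                      hand = hand_k, ...)
  })
}

# threshold for a fiber at a pulse width: stored calibration when available,
# Weiss interpolation otherwise
fiber_threshold <- function(subject, pulse_width, fiber = c("snap", "cmap")) {
  fiber <- match.arg(fiber)
  map <- if (fiber == "snap") subject$snap_threshold else subject$cmap_threshold
  key <- as.character(pulse_width)
  hit <- match(key, names(map))
  if (!is.na(hit)) return(unname(map[hit]))
  base <- weiss_threshold(subject[[paste0("rheobase_", fiber)]],
                          subject[[paste0("chronaxie_", fiber)]], pulse_width)
  base
}

#' Sigmoidal recruitment amplitude
#'
#' Response amplitude of the SNAP or CMAP as a function of stimulation
#' intensity: `max / (1 + exp(-(I - I50) / slope))` with the half-activation
#' point two sigmoid scales above the detectable threshold
#' (`I50 = threshold + 2 * slope`), so the first detectable response
#' (~12 percent of maximum) sits at the calibrated threshold intensity.
#' Monotone non-decreasing in intensity and essentially zero at rest.
#'
#' @param intensity Stimulation intensity in mA (>= 0), vectorized.
#' @param pulse_width Pulse width in ms.
#' @param fiber `"snap"` or `"cmap"`.
#' @param subject A [subject_params] object.
#' @return Amplitude in a.u.
#' @export
recruitment_amplitude <- function(intensity, pulse_width, fiber = c("snap", "cmap"),
                                  subject = subject_params()) {
  fiber <- match.arg(fiber)
  if (any(intensity < 0)) stop("intensity must be >= 0", call. = FALSE)
  thr <- fiber_threshold(subject, pulse_width, fiber)
  I50 <- thr + 2 * subject$recruit_slope
  amp_max <- if (fiber == "snap") subject$snap_max else subject$cmap_max
  amp_max / (1 + exp(-(intensity - I50) / subject$recruit_slope))
}

#' Stimulation protocol parameters
#'
#' @param pulse_width Pulse width in ms (one of the calibrated conditions by
#'   default).
#' @param isi_mean Mean inter-stimulus interval in s (default 2).
#' @param isi_jitter_frac Uniform jitter as a fraction of the mean ISI
#'   (default 0.1, i.e. 1.8-2.2 s).
#' @param n_trials Number of assessment trials (default 70, the study cap).
#' @param intensity_step_recruit Recruitment-curve step in mA (default 0.5).
#' @param intensity_step_assess Assessment adjustment step in mA (default 0.1).
#' @param trials_per_step Trials per recruitment step (default 4).
#' @param seed Integer seed.
#' @return A `stimulation_protocol` list.
#' @export
stimulation_protocol <- function(pulse_width = 1, isi_mean = 2,
                                 isi_jitter_frac = 0.1, n_trials = 70,
                                 intensity_step_recruit = 0.5,
                                 intensity_step_assess = 0.1,
                                 trials_per_step = 4, seed = 1L) {
  stopifnot(isi_mean > 0, isi_jitter_frac >= 0, isi_jitter_frac < 1,
            n_trials >= 1, trials_per_step >= 1)
  structure(list(pulse_width = pulse_width, isi_mean = isi_mean,
                 isi_jitter_frac = isi_jitter_frac, n_trials = n_trials,
                 intensity_step_recruit = intensity_step_recruit,
                 intensity_step_assess = intensity_step_assess,
                 trials_per_step = trials_per_step, seed = as.integer(seed)),
            class = "stimulation_protocol")
}

#' Jittered stimulus onset train
#'
#' Stimulus onset times whose successive intervals are i.i.d. uniform on
#' `isi_mean * (1 +/- isi_jitter_frac)` (1.8-2.2 s at the defaults, a mean
#' rate of 0.5 Hz).
#'
#' @param n Number of stimuli (>= 1).
#' @param protocol A [stimulation_protocol] (supplies mean ISI and jitter).
#' @param seed Integer seed (defaults to the protocol seed).
#' @return Onset times in seconds (first onset one ISI after t = 0).
#' @export
generate_isi_train <- function(n, protocol = stimulation_protocol(), seed = protocol$seed) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  lo <- protocol$isi_mean * (1 - protocol$isi_jitter_frac)
  hi <- protocol$isi_mean * (1 + protocol$isi_jitter_frac)
  isi <- with_seed(seed, stats::runif(n, lo, hi))
  cumsum(isi)
}

# EMG epoch grid constants: [-50, 50) ms at 3200 Hz
emg_fs <- 3200
emg_window <- c(-50, 50)

# latencies snapped to the 3200 Hz grid (3.75 and 5.9375 ms)
snap_latency_ms <- round(3.8 * emg_fs / 1000) / emg_fs * 1000
cmap_latency_ms <- round(6.0 * emg_fs / 1000) / emg_fs * 1000

#' Synthesize one EMG trial (SNAP and CMAP channels)
#'
#' Generates the digit (SNAP) and thenar (CMAP) traces of one stimulation
#' trial on the [-50, 50) ms epoch grid at 3200 Hz: a brief high-frequency
#' stimulus artifact at t ~ 0 on both channels, a biphasic SNAP wavelet
#' peaking at 3.75 ms (the 3.8 ms target snapped to the sample grid) and a
#' slower CMAP wavelet peaking at 5.94 ms, with sigmoidal recruitment
#' amplitudes, multiplicative trial-to-trial amplitude variability, and
#' band-limited (10-1000 Hz) Gaussian background. With `noise = FALSE` the
#' idealized noiseless trace is returned and the peaks equal the recruitment
#' amplitudes exactly.
#'
#' @param intensity Stimulation intensity in mA.
#' @param pulse_width Pulse width in ms.
#' @param subject A [subject_params].
#' @param seed Integer seed for this trial.
#' @param noise Logical; disable all stochastic elements with `FALSE`.
#' @return List with `snap`, `cmap` (numeric traces), `times_ms`, and `truth`
#'   (data frame: drawn SNAP/CMAP amplitudes and latencies).
#' @export
synth_emg_trial <- function(intensity, pulse_width, subject = subject_params(),
                            seed = 1L, noise = TRUE) {
  n <- floor(emg_window[2] * emg_fs / 1000) - floor(emg_window[1] * emg_fs / 1000)
  t <- epoch_times(n, emg_fs, emg_window[1])
  base_snap <- recruitment_amplitude(intensity, pulse_width, "snap", subject)
  base_cmap <- recruitment_amplitude(intensity, pulse_width, "cmap", subject)
  if (noise) {
    draw <- with_seed(seed, {
      list(z = stats::rnorm(2), eps_snap = stats::rnorm(n), eps_cmap = stats::rnorm(n),
           q = stats::rnorm(2 * n, sd = 0.02))
    })
    amp_snap <- base_snap * max(0, 1 + subject$amp_cv * draw$z[1])
    amp_cmap <- base_cmap * max(0, 1 + subject$amp_cv * draw$z[2])
  } else {
    amp_snap <- base_snap; amp_cmap <- base_cmap
  }
  artifact <- (2 * intensity) * gausscos(t, 0.4, 0.15, 700) * (t >= -1 & t <= 2)
  snap_clean <- amp_snap * gausscos(t, snap_latency_ms, 0.8, 250)
  cmap_clean <- amp_cmap * gausscos(t, cmap_latency_ms, 1.5, 150)
  if (noise) {
    hw <- signal::butter(2, c(10, 1000) / (emg_fs / 2), type = "pass")
    snap_tr <- zero_phase(hw, snap_clean + artifact +
                            subject$emg_noise_sd * draw$eps_snap, n - 1) +
      draw$q[seq_len(n)]
    cmap_tr <- zero_phase(hw, cmap_clean + artifact +
                            subject$emg_noise_sd * draw$eps_cmap, n - 1) +
      draw$q[n + seq_len(n)]
  } else {
    snap_tr <- snap_clean + artifact
    cmap_tr <- cmap_clean + artifact
  }
  list(snap = snap_tr, cmap = cmap_tr, times_ms = t,
       truth = data.frame(snap_amp = amp_snap, cmap_amp = amp_cmap,
                          snap_lat = snap_latency_ms, cmap_lat = cmap_latency_ms,
                          intensity = intensity))
}

#' Synthesize a SNAP/CMAP recruitment session
#'
#' Trials in blocks of `trials_per_step` at intensities rising in 0.5 mA steps
#' around the subject's threshold for the pulse width, packaged as
#' [emg_epochs] per channel plus the generator truth.
#'
#' @param subject A [subject_params].
#' @param pulse_width Pulse width in ms.
#' @param seed Integer seed.
#' @param intensities Optional explicit intensity levels (mA); default spans
#'   threshold - 3 to threshold + 4 mA in 0.5 mA steps, capped at the
#'   discomfort limit.
#' @param protocol A [stimulation_protocol] (for step sizes and block size).
#' @param noise Passed to [synth_emg_trial()].
#' @return List with `snap`, `cmap` ([emg_epochs] with per-trial intensity)
#'   and `truth` (one row per trial).
#' @export
synth_recruitment_session <- function(subject, pulse_width, seed = 1L,
                                      intensities = NULL,
                                      protocol = stimulation_protocol(pulse_width = pulse_width),
                                      noise = TRUE) {
  thr <- fiber_threshold(subject, pulse_width, "snap")
  if (is.null(intensities)) {
    step <- protocol$intensity_step_recruit
    lo <- max(step, round((thr - 3) / step) * step)
    hi <- min(subject$discomfort_limit, round((thr + 4) / step) * step)
    intensities <- seq(lo, hi, by = step)
  }
  reps <- rep(intensities, each = protocol$trials_per_step)
  trials <- lapply(seq_along(reps), function(i) {
    synth_emg_trial(reps[i], pulse_width, subject,
                    seed = derive_seed(seed, 2L, i), noise = noise)
  })
  snap_mat <- do.call(rbind, lapply(trials, `[[`, "snap"))
  cmap_mat <- do.call(rbind, lapply(trials, `[[`, "cmap"))
  truth <- do.call(rbind, lapply(trials, `[[`, "truth"))
  truth$trial <- seq_len(nrow(truth))
  list(snap = emg_epochs(snap_mat, emg_fs, emg_window, intensity = reps),
       cmap = emg_epochs(cmap_mat, emg_fs, emg_window, intensity = reps),
       truth = truth)
}

#' Closed-loop observer for assessment-run simulation
#'
#' Returns a function `(intensity, trial) -> c(snap, cmap)` that synthesizes a
#' trial at the requested intensity and measures the SNAP/CMAP peak responses
#' the way the monitoring pipeline does (band-pass filtered, peak in the
#' standard windows). An optional multiplicative `drift` profile (one factor
#' per trial) emulates slow changes in effective afferent excitation such as
#' electrode drying or limb repositioning.
#'
#' @param subject A [subject_params].
#' @param pulse_width Pulse width in ms.
#' @param seed Integer seed.
#' @param drift Numeric vector of per-trial gain factors (recycled), default 1.
#' @param noise Passed to [synth_emg_trial()].
#' @param filtered Measure peaks on 100-300 Hz filtered traces (default TRUE).
#' @return Function suitable as `observe` for [monitor_assessment()].
#' @export
synth_assessment_observer <- function(subject, pulse_width, seed = 1L,
                                      drift = 1, noise = TRUE, filtered = TRUE) {
  force(subject); force(pulse_width); force(seed); force(drift)
  function(intensity, trial) {
    tr <- synth_emg_trial(intensity, pulse_width, subject,
                          seed = derive_seed(seed, 3L, trial), noise = noise)
    g <- drift[((trial - 1) %% length(drift)) + 1]
    ep_s <- emg_epochs(matrix(tr$snap * g, 1), emg_fs, emg_window)
    ep_c <- emg_epochs(matrix(tr$cmap * g, 1), emg_fs, emg_window)
    if (filtered) {
      ep_s <- filter_emg(ep_s)
      ep_c <- filter_emg(ep_c)
    }
    c(snap = peak_response(ep_s, c(2, 8))$amplitude,
      cmap = peak_response(ep_c, c(3, 15))$amplitude)
  }
}

# 1/f (power exponent 1) background noise, unit SD, via spectral shaping of
# white Gaussian noise; frequencies below f_floor are flattened to keep the
# variance finite.
colored_noise <- function(n, fs, exponent = 1, f_floor = 0.5) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f) # two-sided frequency magnitude
  shape <- pmax(f, f_floor)^(-exponent / 2)
  shape[1] <- 0 # remove DC
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Synthesize a full EEG stimulation session
#'
#' Generates a 19-channel, 300 Hz referential EEG record for one assessment
#' run at one pulse-width condition: a background of 1/f noise plus 10 Hz
#' alpha and 60 Hz line components per channel, and for each stimulus event a
#' positive Gaussian-windowed P50 component and a negative N70 component on
#' the contralateral central channel (attenuated on its neighbors), with
#' per-trial amplitude variability and latency jitter. Component center
#' latencies are snapped to the sample grid and recorded, together with the
#' drawn amplitudes and the noiseless windowed peak values at the analysis
#' channel, in the returned truth table.
#'
#' @param subject A [subject_params].
#' @param protocol A [stimulation_protocol]; `n_trials` and ISI settings are
#'   honored.
#' @param pulse_width Condition pulse width in ms; must be among the subject's
#'   calibrated conditions.
#' @param seed Integer seed.
#' @param noise Logical; `FALSE` yields the noiseless components only.
#' @param gain Session-level multiplicative gain on component amplitudes
#'   (models session-to-session variability; default 1).
#' @param artifact_fraction Fraction of trials contaminated by a large
#'   broadband artifact burst (default 0).
#' @param neighbor_gain Spatial attenuation of components on Hjorth neighbors
#'   of the target channel (default 0.35; far channels get 0.05).
#' @return A `synthetic_session`: `eeg` ([eeg_recording] with events), `truth`
#'   (per-trial data frame), `pulse_width`, `target_channel`,
#'   `n70_channel` (differs under the impaired profile), `onsets_s`.
#' @export
synth_eeg_session <- function(subject, protocol = stimulation_protocol(),
                              pulse_width = protocol$pulse_width, seed = 1L,
                              noise = TRUE, gain = 1, artifact_fraction = 0,
                              neighbor_gain = 0.35) {
  key <- as.character(pulse_width)
  if (!key %in% names(subject$p50_amp)) {
    stop("pulse width ", pulse_width, " not among calibrated conditions", call. = FALSE)
  }
  fs <- 300
  n_trials <- protocol$n_trials
  onsets <- generate_isi_train(n_trials, protocol, seed = derive_seed(seed, 4L))
  pre_pad <- 2; post_pad <- 1.5
  n_samp <- ceiling((pre_pad + onsets[n_trials] + post_pad) * fs)
  events <- as.integer(round((pre_pad + onsets) * fs)) + 1L
  labels <- montage_1020
  n_ch <- length(labels)

  target <- contralateral_channel(subject$hand)
  n70_target <- if (subject$impaired) (if (target == "C4") "P4" else "P3") else target
  n70_scale <- if (subject$impaired) 0.5 else 1

  spatial_weights <- function(center) {
    w <- stats::setNames(rep(0.05, n_ch), labels)
    w[center] <- 1
    nb <- intersect(hjorth_neighbors[[center]], labels)
    w[nb] <- neighbor_gain
    w
  }
  w_p50 <- spatial_weights(target)
  w_n70 <- spatial_weights(n70_target)

  data <- matrix(0, n_ch, n_samp)
  if (noise) {
    bg <- with_seed(derive_seed(seed, 5L), {
      tsec <- (seq_len(n_samp) - 1) / fs
      sapply(seq_len(n_ch), function(ch) {
        pink <- colored_noise(n_samp, fs)
        phases <- stats::runif(2, 0, 2 * pi)
        subject$eeg_noise_sd * (pink +
          0.5 * sin(2 * pi * 10 * tsec + phases[1]) +
          0.5 * sin(2 * pi * 60 * tsec + phases[2]))
      })
    })
    data <- data + t(bg)
  }

  amp_p50_mean <- gain * unname(subject$p50_amp[key])
  amp_n70_mean <- gain * n70_scale * unname(subject$n70_amp[key])
  p50_sigma <- 10; n70_sigma <- 12

  truth <- data.frame(trial = seq_len(n_trials), event_sample = events,
                      p50_amp = NA_real_, n70_amp = NA_real_,
                      p50_lat = NA_real_, n70_lat = NA_real_,
                      artifact = FALSE)
  draws <- with_seed(derive_seed(seed, 6L), {
    list(zp = stats::rnorm(n_trials), zn = stats::rnorm(n_trials),
         lp = stats::rnorm(n_trials), ln = stats::rnorm(n_trials),
         art = stats::runif(n_trials))
  })
  for (tr in seq_len(n_trials)) {
    if (noise) {
      a_p50 <- amp_p50_mean * max(0, 1 + subject$amp_cv * draws$zp[tr])
      a_n70 <- amp_n70_mean * max(0, 1 + subject$amp_cv * draws$zn[tr])
      l_p50 <- subject$p50_lat + subject$lat_jitter_sd * draws$lp[tr]
      l_n70 <- subject$n70_lat + subject$lat_jitter_sd * draws$ln[tr]
      if (l_n70 - l_p50 < 10) l_n70 <- l_p50 + 10 # keep component order
    } else {
      a_p50 <- amp_p50_mean; a_n70 <- amp_n70_mean
      l_p50 <- subject$p50_lat; l_n70 <- subject$n70_lat
    }
    # snap component centers to the sample grid
    c_p50 <- events[tr] + round(l_p50 * fs / 1000)
    c_n70 <- events[tr] + round(l_n70 * fs / 1000)
    idx <- max(1, events[tr] - 30):min(n_samp, events[tr] + 150)
    k_p50 <- a_p50 * exp(-((idx - c_p50) / (p50_sigma * fs / 1000))^2 / 2)
    k_n70 <- a_n70 * exp(-((idx - c_n70) / (n70_sigma * fs / 1000))^2 / 2)
    data[, idx] <- data[, idx] + outer(w_p50, k_p50) + outer(w_n70, k_n70)
    truth$p50_amp[tr] <- a_p50; truth$n70_amp[tr] <- a_n70
    truth$p50_lat[tr] <- (c_p50 - events[tr]) * 1000 / fs
    truth$n70_lat[tr] <- (c_n70 - events[tr]) * 1000 / fs
    truth$artifact[tr] <- noise && artifact_fraction > 0 && draws$art[tr] < artifact_fraction
  }
  if (any(truth$artifact)) {
    art_noise <- with_seed(derive_seed(seed, 7L), {
      lapply(which(truth$artifact), function(tr) stats::rnorm(105))
    })
    for (i in seq_along(art_noise)) {
      tr <- which(truth$artifact)[i]
      idx <- (events[tr] - 15):(events[tr] + 89)
      data[, idx] <- data[, idx] +
        10 * subject$eeg_noise_sd * matrix(rep(art_noise[[i]], each = n_ch), n_ch)
    }
  }

  # noiseless windowed peaks at the analysis channel (baseline-corrected),
  # the reference the averaged-SEP path should recover exactly on clean data
  truth$p50_peak_clean <- NA_real_; truth$n70_peak_clean <- NA_real_
  rel <- -15:89 # [-50, 300) ms at 300 Hz
  # same floor-based half-open window convention as the analysis side
  p50_win <- rel >= floor(25 * fs / 1000) & rel < floor(65 * fs / 1000)
  n70_win <- rel >= floor(55 * fs / 1000) & rel < floor(95 * fs / 1000)
  base_win <- rel >= floor(-50 * fs / 1000) & rel < 0
  for (tr in seq_len(n_trials)) {
    cp <- round(truth$p50_lat[tr] * fs / 1000)
    cn <- round(truth$n70_lat[tr] * fs / 1000)
    clean <- truth$p50_amp[tr] * exp(-((rel - cp) / (p50_sigma * fs / 1000))^2 / 2) +
      truth$n70_amp[tr] * exp(-((rel - cn) / (n70_sigma * fs / 1000))^2 / 2)
    # the N70 target weight at the P50 channel differs under impairment
    if (n70_target != target) {
      clean <- truth$p50_amp[tr] * exp(-((rel - cp) / (p50_sigma * fs / 1000))^2 / 2) +
        w_n70[target] * truth$n70_amp[tr] * exp(-((rel - cn) / (n70_sigma * fs / 1000))^2 / 2)
    }
    clean <- clean - mean(clean[base_win])
    truth$p50_peak_clean[tr] <- max(clean[p50_win])
    truth$n70_peak_clean[tr] <- min(clean[n70_win])
  }

  rec <- eeg_recording(data, fs, labels, events)
  structure(list(eeg = rec, truth = truth, pulse_width = pulse_width,
                 target_channel = target, n70_channel = n70_target,
                 onsets_s = onsets, seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("Synthetic EEG session: %d trials at %g ms pulse width, analysis channel %s\n",
              nrow(x$truth), x$pulse_width, x$target_channel))
  invisible(x)
}
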