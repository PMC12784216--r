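# SNAP/CMAP processing: filtering, epoching, background estimation, peak
# responses, recruitment curves, the target-intensity rule, assessment-run
# maintenance, and charge computation.

#' Epoched EMG trials
#'
#' Container for stimulus-locked EMG epochs (one nerve or muscle channel).
#' The epoch window is half-open in ms with the stimulus at 0; sample index
#' for time t is `floor(t * fs / 1000)`.
#'
#' @param data Numeric matrix, trials x samples.
#' @param fs Sampling rate in Hz (default 3200).
#' @param window Epoch window in ms, default `c(-50, 50)`.
#' @param intensity Per-trial stimulation intensity in mA (length = trials).
#' @return An `emg_epochs` object.
#' @export
emg_epochs <- function(data, fs = 3200, window = c(-50, 50), intensity = NULL) {
  data <- as.matrix(data)
  stopifnot(window[1] < 0, window[2] > 0)
  expected <- floor(window[2] * fs / 1000) - floor(window[1] * fs / 1000)
  if (ncol(data) != expected) {
    stop(sprintf("expected %d samples per epoch for window [%g, %g) at %g Hz",
                 expected, window[1], window[2], fs), call. = FALSE)
  }
  if (!is.null(intensity) && length(intensity) != nrow(data)) {
    stop("intensity must have one value per trial", call. = FALSE)
  }
  structure(list(data = data, fs = fs, window = window, intensity = intensity),
            class = "emg_epochs")
}

#' @export
print.emg_epochs <- function(x, ...) {
  cat(sprintf("EMG epochs: %d trials x %d samples, %g Hz, window [%g, %g) ms\n",
              nrow(x$data), ncol(x$data), x$fs, x$window[1], x$window[2]))
  invisible(x)
}

#' Band-pass filter EMG traces (100-300 Hz, zero-phase)
#'
#' Second-order Butterworth band-pass applied forward-backward (zero phase).
#' Accepts a vector (one trace), a matrix (one trace per row), or
#' [emg_epochs]. For epoched input the stimulation-artifact interval
#' (default 0-1.5 ms) is blanked by linear interpolation before filtering,
#' so the broadband artifact does not ring into the SNAP/CMAP windows.
#'
#' @param x Trace(s) to filter.
#' @param fs Sampling rate in Hz (>= 800; taken from the object for
#'   `emg_epochs` input).
#' @param band Passband edges in Hz, default `c(100, 300)`.
#' @param blank Half-open blanking window in ms around the stimulus (only for
#'   `emg_epochs` input; `NULL` disables).
#' @return Filtered object of the same shape/class.
#' @export
filter_emg <- function(x, fs = 3200, band = c(100, 300), blank = c(0, 1.5)) {
  if (inherits(x, "emg_epochs")) {
    dat <- x$data
    if (!is.null(blank)) {
      idx <- window_index(blank, x$fs, x$window[1])
      lo <- min(idx) - 1L; hi <- max(idx) + 1L
      for (i in seq_len(nrow(dat))) {
        dat[i, idx] <- dat[i, lo] +
          (dat[i, hi] - dat[i, lo]) * (idx - lo) / (hi - lo)
      }
    }
    x$data <- filter_emg(dat, x$fs, band)
    return(x)
  }
  if (fs < 800) stop("sampling rate too low for the 100-300 Hz band", call. = FALSE)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  pad <- round(0.05 * fs) # ~10 time constants of the 100 Hz corner
  ff <- function(v) zero_phase(bf, v, pad)
  if (is.matrix(x)) t(apply(x, 1, ff)) else ff(as.numeric(x))
}

#' Pre-stimulus background level of rectified EMG
#'
#' Background response statistics from the pre-stimulus part of each epoch:
#' the samples in the background window (default -50 to -15 ms) are rectified
#' and, by default, pooled across trials; the returned level is the median of
#' that pool and the SD is computed on the same pool. `method = "per_trial"`
#' instead takes per-trial medians and summarizes those across trials.
#'
#' @param epochs An [emg_epochs] object whose window covers the background
#'   window.
#' @param window Background window in ms, default `c(-50, -15)`.
#' @param method `"pooled"` (default) or `"per_trial"`.
#' @return A list with `median` and `sd` (both in signal units).
#' @export
background_level <- function(epochs, window = c(-50, -15), method = c("pooled", "per_trial")) {
  method <- match.arg(method)
  stopifnot(inherits(epochs, "emg_epochs"))
  if (window[1] < epochs$window[1] || window[2] > epochs$window[2]) {
    stop("background window outside epoch window", call. = FALSE)
  }
  idx <- window_index(window, epochs$fs, epochs$window[1])
  if (length(idx) == 0) stop("empty background window", call. = FALSE)
  seg <- abs(epochs$data[, idx, drop = FALSE])
  if (method == "pooled") {
    list(median = stats::median(seg), sd = stats::sd(as.numeric(seg)))
  } else {
    med <- apply(seg, 1, stats::median)
    list(median = stats::median(med), sd = stats::sd(med))
  }
}

#' Per-trial peak response within a time window
#'
#' Peak value of the signal within an investigator-determined window (not
#' peak-to-peak). Returns the signed amplitude and the latency of the peak;
#' on ties the earliest latency wins.
#'
#' @param epochs An [emg_epochs] object.
#' @param window Half-open window in ms (inside the epoch window).
#' @param polarity `"max"` (default), `"min"`, or `"absmax"`.
#' @return Data frame with one row per trial: `trial`, `amplitude`,
#'   `latency_ms`, and `intensity` when the epochs carry it.
#' @export
peak_response <- function(epochs, window = c(2, 8), polarity = c("max", "min", "absmax")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(epochs, "emg_epochs"))
  if (window[1] < epochs$window[1] || window[2] > epochs$window[2]) {
    stop("peak window outside epoch window", call. = FALSE)
  }
  idx <- window_index(window, epochs$fs, epochs$window[1])
  times <- epoch_times(ncol(epochs$data), epochs$fs, epochs$window[1])[idx]
  seg <- epochs$data[, idx, drop = FALSE]
  key <- switch(polarity, max = seg, min = -seg, absmax = abs(seg))
  pick <- apply(key, 1, which.max) # which.max returns the earliest tie
  n <- nrow(seg)
  out <- data.frame(trial = seq_len(n),
                    amplitude = seg[cbind(seq_len(n), pick)],
                    latency_ms = times[pick])
  if (polarity == "min") out$amplitude <- out$amplitude
  if (!is.null(epochs$intensity)) out$intensity <- epochs$intensity
  out
}

#' Build a SNAP or CMAP recruitment curve
#'
#' Groups per-trial peak responses by stimulation intensity (acquired in
#' blocks of up to four trials per 0.5 mA step) and averages within each
#' level. Background statistics from the pre-stimulus window are attached for
#' the target-intensity rule.
#'
#' @param epochs An [emg_epochs] object carrying per-trial `intensity`.
#' @param window Peak window in ms (e.g. `c(2, 8)` for SNAP, `c(3, 15)` for
#'   CMAP).
#' @param polarity Peak polarity, see [peak_response()].
#' @param background_window Window for [background_level()].
#' @return A `recruitment_curve` object: `intensities` (ascending), `mean`
#'   response per level, `trials` (per-trial peaks with intensity),
#'   `n_per_level`, `background` (median, sd), `target_intensity` (NA until
#'   set by [detect_target_intensity()]).
#' @export
build_recruitment_curve <- function(epochs, window = c(2, 8),
                                    polarity = "max",
                                    background_window = c(-50, -15)) {
  stopifnot(inherits(epochs, "emg_epochs"))
  if (is.null(epochs$intensity)) stop("epochs carry no intensity log", call. = FALSE)
  peaks <- peak_response(epochs, window, polarity)
  levels <- sort(unique(epochs$intensity))
  if (length(levels) < 2) stop("need at least 2 intensity levels", call. = FALSE)
  m <- tapply(peaks$amplitude, epochs$intensity, mean)
  nlev <- tapply(peaks$amplitude, epochs$intensity, length)
  if (any(nlev > 4)) warning("more than 4 trials at some intensity level")
  bg <- background_level(epochs, background_window)
  structure(list(intensities = levels,
                 mean = as.numeric(m[as.character(levels)]),
                 n_per_level = as.integer(nlev[as.character(levels)]),
                 trials = peaks,
                 background = bg,
                 window = window,
                 target_intensity = NA_real_),
            class = "recruitment_curve")
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat(sprintf("Recruitment curve: %d levels (%g-%g mA), background median %.3g (sd %.3g)\n",
              length(x$intensities), min(x$intensities), max(x$intensities),
              x$background$median, x$background$sd))
  if (!is.na(x$target_intensity)) {
    cat(sprintf("  target intensity: %.1f mA\n", x$target_intensity))
  }
  invisible(x)
}

# levels at which the response is "consistently discernable": peak exceeds
# background median + 3 SD in at least 3 of 4 trials (all trials when fewer
# than 4 were acquired at a level)
discernable_levels <- function(curve, k_sd = 3, min_success = 3) {
  crit <- curve$background$median + k_sd * curve$background$sd
  vapply(curve$intensities, function(I) {
    amps <- curve$trials$amplitude[curve$trials$intensity == I]
    need <- if (length(amps) >= 4) min_success else length(amps)
    sum(amps > crit) >= need
  }, logical(1))
}

#' Target-intensity rule from recruitment curves
#'
#' The smallest intensity that elicited a consistently discernable SNAP (peak
#' more than three background SDs above the background median in at least 3
#' out of 4 trials) along with a consistently discernable CMAP at the same
#' level (same 3-SD rule applied to the CMAP curve). Returns `NA` when no
#' level qualifies; absence is a value, not an error.
#'
#' @param snap_curve SNAP `recruitment_curve`.
#' @param cmap_curve Optional CMAP `recruitment_curve` over the same levels;
#'   when `NULL` the SNAP criterion alone decides.
#' @param k_sd Criterion multiplier (default 3).
#' @return Target intensity in mA, or `NA_real_`.
#' @export
detect_target_intensity <- function(snap_curve, cmap_curve = NULL, k_sd = 3) {
  stopifnot(inherits(snap_curve, "recruitment_curve"))
  ok <- discernable_levels(snap_curve, k_sd)
  if (!is.null(cmap_curve)) {
    stopifnot(inherits(cmap_curve, "recruitment_curve"))
    if (!identical(snap_curve$intensities, cmap_curve$intensities)) {
      stop("SNAP and CMAP curves cover different intensity levels", call. = FALSE)
    }
    ok <- ok & discernable_levels(cmap_curve, k_sd)
  }
  if (!any(ok)) return(NA_real_)
  snap_curve$intensities[which(ok)[1]]
}

#' Assessment-run monitoring of effective afferent excitation
#'
#' Runs (or replays) an assessment run while holding the CMAP within +/- 20
#' percent of the target CMAP, which in turn maintains the SNAP within its
#' band. The intensity is adjusted by 0.1 mA after two consecutive
#' out-of-band trials deviating in the same direction, and then kept at the
#' new level unless/until another change is required. The delivered intensity
#' never exceeds `discomfort_limit`.
#'
#' @param observe Either a function `(intensity, trial) -> c(snap, cmap)`
#'   giving the measured peak responses of a delivered trial (closed loop), or
#'   a data frame / matrix with columns `snap`, `cmap` to be replayed open
#'   loop.
#' @param n_trials Number of trials (default 70; ignored for replayed data).
#' @param start_intensity Starting intensity in mA.
#' @param target_snap,target_cmap Target peak responses (> 0).
#' @param band Relative tolerance band, default 0.2.
#' @param step Adjustment step in mA, default 0.1.
#' @param patience Consecutive out-of-band trials (same direction) before an
#'   adjustment, default 2.
#' @param discomfort_limit Maximum intensity in mA (default `Inf`).
#' @return An `assessment_log` data frame: per trial `intensity`, `snap`,
#'   `cmap`, `in_band`, `adjustment` (the change applied after this trial:
#'   0 or +/- `step`).
#' @export
monitor_assessment <- function(observe, n_trials = 70, start_intensity,
                               target_snap, target_cmap, band = 0.2,
                               step = 0.1, patience = 2,
                               discomfort_limit = Inf) {
  stop_if_not_positive(target_snap = target_snap, target_cmap = target_cmap)
  replay <- NULL
  if (!is.function(observe)) {
    replay <- as.data.frame(observe)
    if (!all(c("snap", "cmap") %in% names(replay))) {
      stop("replayed trials need 'snap' and 'cmap' columns", call. = FALSE)
    }
    n_trials <- nrow(replay)
  }
  intensity <- start_intensity
  out <- data.frame(trial = seq_len(n_trials), intensity = NA_real_,
                    snap = NA_real_, cmap = NA_real_, in_band = NA,
                    adjustment = 0)
  run_dir <- 0L; run_len <- 0L
  for (t in seq_len(n_trials)) {
    obs <- if (is.null(replay)) observe(intensity, t) else unlist(replay[t, c("snap", "cmap")])
    snap <- obs[[1]]; cmap <- obs[[2]]
    dev <- (cmap - target_cmap) / target_cmap
    in_band <- abs(dev) <= band
    adj <- 0
    if (in_band) {
      run_dir <- 0L; run_len <- 0L
    } else {
      dir <- if (dev < 0) 1L else -1L # CMAP sagged -> increase intensity
      if (dir == run_dir) run_len <- run_len + 1L else { run_dir <- dir; run_len <- 1L }
      if (run_len >= patience) {
        adj <- dir * step
        run_dir <- 0L; run_len <- 0L
      }
    }
    out$intensity[t] <- intensity
    out$snap[t] <- snap; out$cmap[t] <- cmap
    out$in_band[t] <- in_band
    out$adjustment[t] <- adj
    intensity <- min(max(intensity + adj, 0), discomfort_limit)
  }
  class(out) <- c("assessment_log", "data.frame")
  out
}

#' Delivered charge per pulse
#'
#' Charge (coulombs) = pulse width (seconds) x current (amperes), with inputs
#' in the units used at the bedside (mA and ms).
#'
#' @param current_ma Stimulation current in mA (>= 0).
#' @param pulse_width_ms Pulse width in ms (>= 0).
#' @return Charge in coulombs.
#' @examples
#' compute_charge(8.3, 1) # 8.30e-06 C
#' compute_charge(9.5, 0.5) # 4.75e-06 C
#' @export
compute_charge <- function(current_ma, pulse_width_ms) {
  if (any(current_ma < 0) || any(pulse_width_ms < 0)) {
    stop("current and pulse width must be non-negative", call. = FALSE)
  }
  (current_ma * 1e-3) * (pulse_width_ms * 1e-3)
}
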