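# EEG preprocessing and averaged-SEP analysis: bad-channel rejection, notch +
# band-pass Butterworth filtering (zero phase), Hjorth surface Laplacian,
# epoching with per-trial baseline correction, bad-trial masking, P50/N70
# peak extraction, and r-squared topography.

#' Standard 19-channel 10-20 montage labels
#' @export
montage_1020 <- c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "Cz", "C3",
                  "C4", "T7", "T8", "Pz", "P3", "P4", "P7", "P8", "O1", "O2")

# Hjorth (nearest-neighbor) sets for the 19-channel 10-20 montage
hjorth_neighbors <- list(
  Fp1 = c("Fp2", "Fz", "F3", "F7"),
  Fp2 = c("Fp1", "Fz", "F4", "F8"),
  Fz  = c("F3", "F4", "Cz", "Fp1", "Fp2"),
  F3  = c("Fp1", "Fz", "C3", "F7"),
  F4  = c("Fp2", "Fz", "C4", "F8"),
  F7  = c("Fp1", "F3", "T7"),
  F8  = c("Fp2", "F4", "T8"),
  Cz  = c("Fz", "C3", "C4", "Pz"),
  C3  = c("F3", "P3", "Cz", "T7"),
  C4  = c("F4", "P4", "Cz", "T8"),
  T7  = c("F7", "C3", "P7"),
  T8  = c("F8", "C4", "P8"),
  Pz  = c("Cz", "P3", "P4"),
  P3  = c("C3", "Pz", "P7", "O1"),
  P4  = c("C4", "O2", "Pz", "P8"),
  P7  = c("T7", "P3", "O1"),
  P8  = c("T8", "P4", "O2"),
  O1  = c("P7", "P3", "O2"),
  O2  = c("P8", "P4", "O1")
)

#' Continuous multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (default 300).
#' @param labels Channel labels (10-20 names), unique, one per row.
#' @param events Stimulus onset sample indices (1-based), strictly increasing,
#'   within the record.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs = 300, labels = montage_1020, events = integer()) {
  data <- as.matrix(data)
  if (length(labels) != nrow(data)) stop("one label per channel required", call. = FALSE)
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  events <- as.integer(events)
  if (length(events) && (any(events < 1) || any(events > ncol(data)))) {
    stop("event indices outside the record", call. = FALSE)
  }
  if (is.unsorted(events, strictly = TRUE)) stop("event indices must be strictly increasing", call. = FALSE)
  structure(list(data = data, fs = fs, labels = labels, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, length(x$events)))
  invisible(x)
}

#' Reject bad channels by robust amplitude
#'
#' Channels whose robust amplitude (median absolute deviation of the trace)
#' exceeds `k` times the montage median MAD, or whose variance is essentially
#' zero (flat), are removed. Losing the contralateral analysis channel is a
#' hard error since the SEP analysis cannot proceed without it.
#'
#' @param recording An [eeg_recording] with at least 8 channels.
#' @param k Rejection multiplier on the montage median MAD (default 4).
#' @param protect Channels whose rejection aborts the analysis (default C3/C4).
#' @return The recording without the rejected channels, with the rejected
#'   labels in attribute `"rejected"`.
#' @export
reject_bad_channels <- function(recording, k = 4, protect = c("C3", "C4")) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$data) < 8) stop("need at least 8 channels", call. = FALSE)
  mads <- apply(recording$data, 1, stats::mad)
  ref <- stats::median(mads)
  flat <- apply(recording$data, 1, stats::var) < 1e-20
  bad <- flat | (mads > k * ref)
  lost <- intersect(recording$labels[bad], protect)
  if (length(lost)) {
    stop("analysis channel rejected: ", paste(lost, collapse = ", "), call. = FALSE)
  }
  out <- eeg_recording(recording$data[!bad, , drop = FALSE], recording$fs,
                       recording$labels[!bad], recording$events)
  attr(out, "rejected") <- recording$labels[bad]
  out
}

butter_sos <- function(order, edges, fs, type) {
  signal::butter(order, edges / (fs / 2), type = type)
}

#' Notch + band-pass EEG preprocessing
#'
#' Zero-phase (forward-backward) filtering with second-order Butterworth
#' prototypes: a 55-65 Hz band-stop (line noise) followed by a 2-40 Hz
#' band-pass.
#'
#' @param recording An [eeg_recording].
#' @param notch Band-stop edges in Hz, default `c(55, 65)`.
#' @param band Band-pass edges in Hz, default `c(2, 40)`.
#' @return Filtered recording.
#' @export
preprocess_eeg <- function(recording, notch = c(55, 65), band = c(2, 40)) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$fs / 2
  if (max(notch) >= nyq || max(band) >= nyq) {
    stop("filter edge at or above Nyquist", call. = FALSE)
  }
  bs <- butter_sos(2, notch, recording$fs, "stop")
  bp <- butter_sos(2, band, recording$fs, "pass")
  pad <- round(3 * recording$fs / min(band)) # ~3 periods of the low corner
  recording$data <- t(apply(recording$data, 1, function(v) {
    zero_phase(bp, zero_phase(bs, v, pad), pad)
  }))
  recording
}

#' Hjorth surface Laplacian of one channel
#'
#' Spatial high-pass derivation: the channel minus the mean of its available
#' nearest 10-20 neighbors. Neighbor sets are fixed by the montage table
#' (e.g. C4: F4, P4, Cz, T8). At least two neighbors must be present; when a
#' neighbor is missing (e.g. rejected), the mean is taken over the rest.
#'
#' @param recording An [eeg_recording].
#' @param channel Channel label to derive.
#' @return Numeric trace (one sample per record sample).
#' @export
laplacian <- function(recording, channel) {
  stopifnot(inherits(recording, "eeg_recording"))
  i <- match(channel, recording$labels)
  if (is.na(i)) stop("channel not found: ", channel, call. = FALSE)
  nb <- hjorth_neighbors[[channel]]
  if (is.null(nb)) stop("no neighbor table for channel ", channel, call. = FALSE)
  j <- stats::na.omit(match(nb, recording$labels))
  if (length(j) < 2) stop("fewer than 2 neighbors available for ", channel, call. = FALSE)
  recording$data[i, ] - colMeans(recording$data[j, , drop = FALSE])
}

#' Apply the Hjorth Laplacian to every derivable channel
#'
#' @param recording An [eeg_recording].
#' @return A recording whose channels are each replaced by their Laplacian
#'   derivation; channels with fewer than 2 available neighbors are dropped.
#' @export
laplacian_montage <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  ok <- vapply(recording$labels, function(ch) {
    nb <- hjorth_neighbors[[ch]]
    !is.null(nb) && sum(!is.na(match(nb, recording$labels))) >= 2
  }, logical(1))
  der <- t(vapply(recording$labels[ok], function(ch) laplacian(recording, ch),
                  numeric(ncol(recording$data))))
  eeg_recording(der, recording$fs, recording$labels[ok], recording$events)
}

#' Stimulus-locked EEG epochs with baseline correction
#'
#' Epochs the recording from -50 to 300 ms around each event and subtracts,
#' per trial and channel, the mean of the 50 ms pre-stimulus baseline.
#' Events too close to the record edge are dropped (logged in attribute
#' `"dropped_events"`).
#'
#' @param recording An [eeg_recording] with events.
#' @param window Epoch window in ms, default `c(-50, 300)`.
#' @param baseline Baseline window in ms, default `c(-50, 0)`; must lie inside
#'   `window`. `NULL` skips the per-trial centering, which is appropriate when
#'   downstream measures are window energies ([topography_r2()]): centering on
#'   the pre-stimulus window deflates pre-stimulus energy relative to
#'   post-stimulus energy in autocorrelated background activity, biasing
#'   response-vs-background comparisons on every channel.
#' @return An `eeg_epochs` object: `data` (trials x channels x samples), `fs`,
#'   `window`, `baseline`, `labels`, `mask` (logical; TRUE = retained).
#' @export
epoch_and_baseline <- function(recording, window = c(-50, 300), baseline = c(-50, 0)) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!is.null(baseline) &&
      (baseline[1] < window[1] || baseline[2] > window[2])) {
    stop("baseline must lie inside the epoch window", call. = FALSE)
  }
  fs <- recording$fs
  first <- floor(window[1] * fs / 1000)
  last <- floor(window[2] * fs / 1000) - 1L
  nsamp <- last - first + 1L
  ok <- recording$events + first >= 1 & recording$events + last <= ncol(recording$data)
  dropped <- which(!ok)
  events <- recording$events[ok]
  n_ch <- nrow(recording$data)
  arr <- array(NA_real_, dim = c(length(events), n_ch, nsamp))
  for (t in seq_along(events)) {
    arr[t, , ] <- recording$data[, (events[t] + first):(events[t] + last)]
  }
  if (!is.null(baseline)) {
    bidx <- window_index(baseline, fs, window[1])
    bmean <- apply(arr[, , bidx, drop = FALSE], c(1, 2), mean)
    arr <- arr - array(rep(bmean, nsamp), dim = dim(arr))
  }
  out <- structure(list(data = arr, fs = fs, window = window, baseline = baseline,
                        labels = recording$labels,
                        mask = rep(TRUE, length(events))),
                   class = "eeg_epochs")
  attr(out, "dropped_events") <- dropped
  out
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("EEG epochs: %d trials (%d retained) x %d channels x %d samples, window [%g, %g) ms\n",
              dim(x$data)[1], sum(x$mask), dim(x$data)[2], dim(x$data)[3],
              x$window[1], x$window[2]))
  invisible(x)
}

#' Mask bad trials by robust epoch statistics
#'
#' Trials whose epoch peak-to-peak amplitude or epoch RMS on the analysis
#' channel exceeds the across-trial median + 3 x (1.4826 MAD) are masked.
#' Used only in the averaged-SEP path; the single-trial path bypasses trial
#' denoising to mimic real-time analysis.
#'
#' @param epochs An `eeg_epochs` object with at least 10 trials.
#' @param channel Analysis channel label.
#' @param k Cut in robust SDs (default 3).
#' @return The epochs with an updated `mask`. Warns (and proceeds) if more
#'   than half the trials are masked.
#' @export
reject_bad_trials <- function(epochs, channel, k = 3) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (dim(epochs$data)[1] < 10) stop("need at least 10 trials", call. = FALSE)
  ch <- match(channel, epochs$labels)
  if (is.na(ch)) stop("channel not found: ", channel, call. = FALSE)
  seg <- epochs$data[, ch, , drop = TRUE]
  p2p <- apply(seg, 1, function(v) max(v) - min(v))
  rmsv <- apply(seg, 1, rms)
  cut <- function(v) v > stats::median(v) + k * (1.4826 * stats::mad(v, constant = 1))
  bad <- cut(p2p) | cut(rmsv)
  epochs$mask <- epochs$mask & !bad
  if (mean(!epochs$mask) > 0.5) warning("more than 50% of trials masked")
  epochs
}

#' Averaged SEP and P50/N70 peaks
#'
#' Averages the unmasked trials at one channel and extracts the mid-latency
#' components: P50 as the maximum in the 25-65 ms window, N70 as the minimum
#' in the 55-95 ms window (signed amplitudes, earliest latency on ties).
#'
#' @param epochs An `eeg_epochs` object.
#' @param channel Channel label (spatially filtered contralateral C3/C4 in the
#'   standard pipeline).
#' @param p50_window,n70_window Component windows in ms.
#' @return A list with `trace` (averaged epoch), `times_ms`, `n_trials`
#'   (unmasked count), and `peaks`: data frame with `component`, `amplitude`,
#'   `latency_ms`.
#' @export
average_sep <- function(epochs, channel, p50_window = c(25, 65), n70_window = c(55, 95)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ch <- match(channel, epochs$labels)
  if (is.na(ch)) stop("channel not found: ", channel, call. = FALSE)
  keep <- which(epochs$mask)
  if (length(keep) < 1) stop("no unmasked trials", call. = FALSE)
  avg <- apply(epochs$data[keep, ch, , drop = FALSE], 3, mean)
  times <- epoch_times(dim(epochs$data)[3], epochs$fs, epochs$window[1])
  p50_idx <- window_index(p50_window, epochs$fs, epochs$window[1])
  n70_idx <- window_index(n70_window, epochs$fs, epochs$window[1])
  ip <- p50_idx[which.max(avg[p50_idx])]
  im <- n70_idx[which.min(avg[n70_idx])]
  peaks <- data.frame(component = c("P50", "N70"),
                      amplitude = c(avg[ip], avg[im]),
                      latency_ms = c(times[ip], times[im]),
                      channel = channel)
  list(trace = avg, times_ms = times, n_trials = length(keep), peaks = peaks)
}

#' r-squared topography of a component against background
#'
#' For every channel, pools the per-trial component-window responses (label 1)
#' with the per-trial background-window responses (label 0) and computes the
#' squared Pearson correlation between responses and labels, a spatial
#' signal-to-noise map in `[0, 1]`.
#'
#' Feed epochs built with `baseline = NULL` (see [epoch_and_baseline()]):
#' per-trial baseline centering deflates the background-window energy relative
#' to the response windows in autocorrelated noise and inflates the whole map.
#'
#' @param epochs An `eeg_epochs` object (all trials are used).
#' @param component_window Half-open window in ms (e.g. `c(55, 95)` for N70).
#' @param background_window Background window in ms, default `c(-50, 0)`.
#' @param measure Per-trial response measure: `"absmax"` (default; the
#'   component-peak magnitude, matching peak-based topography maps) or
#'   `"rms"`.
#' @param component_tag Label stored with the map.
#' @return A `topography_map` data frame with `channel` and `r2`.
#' @export
topography_r2 <- function(epochs, component_window, background_window = c(-50, 0),
                          measure = c("absmax", "rms"), component_tag = NA_character_) {
  measure <- match.arg(measure)
  stopifnot(inherits(epochs, "eeg_epochs"))
  cidx <- window_index(component_window, epochs$fs, epochs$window[1])
  bidx <- window_index(background_window, epochs$fs, epochs$window[1])
  f <- switch(measure, rms = rms, absmax = function(v) max(abs(v)))
  n_ch <- dim(epochs$data)[2]
  r2 <- vapply(seq_len(n_ch), function(ch) {
    comp <- apply(epochs$data[, ch, cidx, drop = FALSE], 1, f)
    bg <- apply(epochs$data[, ch, bidx, drop = FALSE], 1, f)
    vals <- c(comp, bg)
    labs <- c(rep(1, length(comp)), rep(0, length(bg)))
    if (stats::var(vals) == 0) return(0)
    stats::cor(vals, labs)^2
  }, numeric(1))
  out <- data.frame(channel = epochs$labels, r2 = r2)
  attr(out, "component") <- component_tag
  class(out) <- c("topography_map", "data.frame")
  out
}
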