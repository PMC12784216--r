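# Single-trial SEP path: windowed RMS features at the spatially filtered
# contralateral electrode and ROC-AUC separability from background epochs.
# Deliberately applies no trial denoising, mirroring a real-time pipeline.

#' Root mean square
#'
#' @param x Non-empty numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty input", call. = FALSE)
  sqrt(mean(x^2))
}

#' Per-trial single-trial SEP features
#'
#' Windowed RMS features from epoched, spatially filtered EEG at one channel:
#' the P50 window (default 25-65 ms), the N70 window (default 55-95 ms), and a
#' per-trial background window (default -50-0 ms). Windows are half-open in ms
#' and converted to samples by floor, so e.g. 25-65 ms spans 12 samples at
#' 300 Hz. No bad-trial masking is applied in this path.
#'
#' @param epochs An [eeg_epochs] object.
#' @param channel Channel label to extract from (e.g. `"C4"`).
#' @param p50_window,n70_window,background_window Half-open windows in ms.
#' @return A `sep_features` data frame with one row per trial and columns
#'   `trial`, `p50_rms`, `n70_rms`, `background_rms`.
#' @export
extract_features <- function(epochs, channel,
                             p50_window = c(25, 65),
                             n70_window = c(55, 95),
                             background_window = c(-50, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ch <- match(channel, epochs$labels)
  if (is.na(ch)) stop("channel not found: ", channel, call. = FALSE)
  fs <- epochs$fs
  nsamp <- dim(epochs$data)[3]
  idx <- lapply(list(p50_window, n70_window, background_window),
                function(w) {
                  i <- window_index(w, fs, epochs$window[1])
                  if (max(i) > nsamp) stop("window outside epoch", call. = FALSE)
                  i
                })
  n_trials <- dim(epochs$data)[1]
  feat <- data.frame(
    trial = seq_len(n_trials),
    p50_rms = apply(epochs$data[, ch, idx[[1]], drop = FALSE], 1, rms),
    n70_rms = apply(epochs$data[, ch, idx[[2]], drop = FALSE], 1, rms),
    background_rms = apply(epochs$data[, ch, idx[[3]], drop = FALSE], 1, rms)
  )
  attr(feat, "channel") <- channel
  attr(feat, "windows") <- list(p50 = p50_window, n70 = n70_window,
                                background = background_window)
  class(feat) <- c("sep_features", "data.frame")
  feat
}

#' ROC AUC separability of component features from background
#'
#' Area under the ROC curve for discriminating component-window features from
#' background-window features, computed by the rank (Mann-Whitney)
#' formulation: the fraction of (component, background) pairs where the
#' component feature is larger, with ties credited 0.5. Invariant under any
#' strictly monotone transform of both samples.
#'
#' @param component Numeric vector of component-window features.
#' @param background Numeric vector of background-window features.
#' @param component_tag Optional label stored in the result.
#' @return A `separability_result` list with `auc`, `n_component`,
#'   `n_background`, and `component`.
#' @export
separability_auc <- function(component, background, component_tag = NA_character_) {
  component <- as.numeric(component); background <- as.numeric(background)
  if (length(component) == 0 || length(background) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(component); n0 <- length(background)
  r <- rank(c(component, background))
  # Mann-Whitney U from the rank sum of the component sample
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  out <- list(auc = U / (n1 * n0), n_component = n1, n_background = n0,
              component = component_tag)
  class(out) <- "separability_result"
  out
}

#' @export
print.separability_result <- function(x, ...) {
  cat(sprintf("ROC AUC%s = %.3f (n = %d vs %d background)\n",
              if (is.na(x$component)) "" else paste0(" [", x$component, "]"),
              x$auc, x$n_component, x$n_background))
  invisible(x)
}

#' Per-condition single-trial separability summary
#'
#' Computes, for each subject and pulse-width condition, the ROC AUC of the
#' P50 and N70 RMS features against the background RMS features, and the group
#' mean and standard error per condition.
#'
#' @param features_by_condition A data frame with columns `subject`,
#'   `pulse_width`, `p50_rms`, `n70_rms`, `background_rms` (one row per trial),
#'   e.g. stacked [extract_features()] outputs.
#' @return A list with `per_subject` (subject x condition AUC table) and
#'   `group` (per-condition mean and SE for each component).
#' @export
condition_summary <- function(features_by_condition) {
  f <- features_by_condition
  req <- c("subject", "pulse_width", "p50_rms", "n70_rms", "background_rms")
  if (!all(req %in% names(f))) {
    stop("features must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  split_key <- interaction(f$subject, f$pulse_width, drop = TRUE)
  per <- do.call(rbind, lapply(split(f, split_key), function(g) {
    data.frame(subject = g$subject[1], pulse_width = g$pulse_width[1],
               auc_p50 = separability_auc(g$p50_rms, g$background_rms)$auc,
               auc_n70 = separability_auc(g$n70_rms, g$background_rms)$auc,
               n_trials = nrow(g))
  }))
  rownames(per) <- NULL
  per <- per[order(per$subject, per$pulse_width), ]
  se <- function(v) stats::sd(v) / sqrt(length(v))
  group <- do.call(rbind, lapply(split(per, per$pulse_width), function(g) {
    data.frame(pulse_width = g$pulse_width[1],
               auc_p50_mean = mean(g$auc_p50),
               auc_p50_se = if (nrow(g) > 1) se(g$auc_p50) else NA_real_,
               auc_n70_mean = mean(g$auc_n70),
               auc_n70_se = if (nrow(g) > 1) se(g$auc_n70) else NA_real_,
               n_subjects = nrow(g))
  }))
  rownames(group) <- NULL
  list(per_subject = per, group = group[order(group$pulse_width), ])
}
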