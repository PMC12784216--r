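# Study orchestration: runs the full per-subject pipeline (recruitment ->
# target detection -> assessment -> EEG preprocessing -> averaged and
# single-trial SEP analysis) over a synthetic cohort and assembles the group
# tables and statistics. All computation happens in the other modules; this
# file is glue.

#' Study configuration
#'
#' @param n_subjects Cohort size (default 12).
#' @param pulse_widths Pulse-width conditions in ms (default 0.1, 0.5, 1).
#' @param n_sessions Sessions per subject (default 2, for test-retest
#'   reliability).
#' @param n_trials Assessment trials per condition (default 70).
#' @param seed Master integer seed.
#' @param session_cv Session-to-session multiplicative amplitude variability
#'   (default 0.06).
#' @param include_emg,include_eeg Toggle the peripheral (SNAP/CMAP) and
#'   cortical (EEG) arms.
#' @param reject_trials Apply bad-trial masking in the averaged-SEP path.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 12, pulse_widths = c(0.1, 0.5, 1),
                         n_sessions = 2, n_trials = 70, seed = 1L,
                         session_cv = 0.06, include_emg = TRUE,
                         include_eeg = TRUE, reject_trials = TRUE) {
  stopifnot(n_subjects >= 1, length(pulse_widths) >= 1, n_sessions >= 1,
            n_trials >= 1)
  structure(list(n_subjects = n_subjects, pulse_widths = pulse_widths,
                 n_sessions = n_sessions, n_trials = n_trials,
                 seed = as.integer(seed), session_cv = session_cv,
                 include_emg = include_emg, include_eeg = include_eeg,
                 reject_trials = reject_trials),
            class = "study_config")
}

run_one_condition <- function(subject, s, sess, pw, config) {
  seed <- config$seed
  pwi <- match(pw, config$pulse_widths)
  gain <- 1 + config$session_cv *
    with_seed(derive_seed(seed, 8L, s, sess), stats::rnorm(1))
  out <- list(subject = s, session = sess, pulse_width = pw, hand = subject$hand)

  if (config$include_emg) {
    emg_seed <- derive_seed(seed, 10L, s, sess, pwi)
    rec <- synth_recruitment_session(subject, pw, seed = emg_seed)
    snap_f <- filter_emg(rec$snap)
    cmap_f <- filter_emg(rec$cmap)
    snap_curve <- build_recruitment_curve(snap_f, window = c(2, 8))
    cmap_curve <- build_recruitment_curve(cmap_f, window = c(3, 15))
    target <- detect_target_intensity(snap_curve, cmap_curve)
    out$target_intensity <- target
    out$calibrated_threshold <- fiber_threshold(subject, pw, "snap")
    if (!is.na(target)) {
      out$charge_c <- compute_charge(target, pw)
      tgt_snap <- snap_curve$mean[snap_curve$intensities == target]
      tgt_cmap <- cmap_curve$mean[cmap_curve$intensities == target]
      log <- monitor_assessment(
        synth_assessment_observer(subject, pw, seed = derive_seed(emg_seed, 1L)),
        n_trials = config$n_trials, start_intensity = target,
        target_snap = tgt_snap, target_cmap = tgt_cmap,
        discomfort_limit = subject$discomfort_limit)
      out$n_adjustments <- sum(log$adjustment != 0)
      out$frac_in_band <- mean(log$in_band)
    }
  }

  if (config$include_eeg) {
    eeg_seed <- derive_seed(seed, 11L, s, sess, pwi)
    proto <- stimulation_protocol(pulse_width = pw, n_trials = config$n_trials,
                                  seed = eeg_seed)
    session <- synth_eeg_session(subject, proto, pw, seed = eeg_seed, gain = gain)
    ch <- session$target_channel
    pre <- preprocess_eeg(session$eeg)
    lap <- laplacian_montage(pre)
    ep <- epoch_and_baseline(lap)
    ep_avg <- if (config$reject_trials) reject_bad_trials(ep, ch) else ep
    sep <- average_sep(ep_avg, ch)
    out$p50_amp <- sep$peaks$amplitude[1]
    out$n70_amp <- sep$peaks$amplitude[2]
    out$p50_lat <- sep$peaks$latency_ms[1]
    out$n70_lat <- sep$peaks$latency_ms[2]
    feats <- extract_features(ep, ch)
    out$auc_p50 <- separability_auc(feats$p50_rms, feats$background_rms)$auc
    out$auc_n70 <- separability_auc(feats$n70_rms, feats$background_rms)$auc
    # per-trial signed window peaks for the SNR of the SEP peaks
    p50_idx <- window_index(c(25, 65), ep$fs, ep$window[1])
    n70_idx <- window_index(c(55, 95), ep$fs, ep$window[1])
    chi <- match(ch, ep$labels)
    p50_trials <- apply(ep$data[, chi, p50_idx, drop = FALSE], 1, max)
    n70_trials <- apply(ep$data[, chi, n70_idx, drop = FALSE], 1, min)
    out$snr_p50 <- snr_mean_std(p50_trials)
    out$snr_n70 <- snr_mean_std(n70_trials)
  }
  out
}

#' Run the full synthetic study
#'
#' For each subject, session, and pulse width: simulate a recruitment run,
#' detect the target intensity, simulate an assessment run under the
#' maintenance controller, synthesize and analyze the EEG session (averaged
#' SEP and single-trial features), then assemble group tables (target
#' intensities with CV and normalized intensities, P50/N70 amplitudes and
#' latencies, test-retest ICCs, per-condition AUC) and repeated-measures
#' statistics. Fully reproducible from the config seed. A failing
#' subject-condition is logged in `gaps` and skipped.
#'
#' @param config A [study_config].
#' @return A `study_report` list: `config`, `runs` (one row per
#'   subject-session-condition), `table1`, `table2`, `table3` (NULL for
#'   single-session configs), `auc`, `stats`, `gaps`, `notes`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cohort <- sample_cohort(config$n_subjects, config$seed)
  rows <- list(); gaps <- list()
  for (s in seq_len(config$n_subjects)) {
    for (sess in seq_len(config$n_sessions)) {
      for (pw in config$pulse_widths) {
        res <- tryCatch(run_one_condition(cohort[[s]], s, sess, pw, config),
                        error = function(e) e)
        if (inherits(res, "error")) {
          gaps[[length(gaps) + 1]] <- list(subject = s, session = sess,
                                           pulse_width = pw,
                                           reason = conditionMessage(res))
        } else {
          rows[[length(rows) + 1]] <- res
        }
      }
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  runs <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    as.data.frame(r[all_cols])
  }))

  se <- function(v) stats::sd(v) / sqrt(length(v))
  notes <- character()
  s1 <- runs[runs$session == 1, , drop = FALSE]

  table1 <- NULL
  if (config$include_emg) {
    norm <- normalized_intensity(s1)
    table1 <- do.call(rbind, lapply(split(s1, s1$pulse_width), function(g) {
      ti <- g$target_intensity[!is.na(g$target_intensity)]
      data.frame(pulse_width = g$pulse_width[1],
                 target_intensity_mean = mean(ti),
                 target_intensity_se = if (length(ti) > 1) se(ti) else NA_real_,
                 cv = if (length(ti) > 1) coefficient_of_variation(ti) else NA_real_,
                 charge_c = mean(compute_charge(ti, g$pulse_width[1])),
                 n = length(ti))
    }))
    table1 <- merge(table1, norm$group, by = "pulse_width", all.x = TRUE)
    rownames(table1) <- NULL
  }

  table2 <- NULL
  auc_tbl <- NULL
  stats_out <- list()
  if (config$include_eeg) {
    table2 <- do.call(rbind, lapply(split(s1, s1$pulse_width), function(g) {
      data.frame(pulse_width = g$pulse_width[1],
                 p50_amp_mean = mean(g$p50_amp), p50_amp_se = se(g$p50_amp),
                 n70_amp_mean = mean(g$n70_amp), n70_amp_se = se(g$n70_amp),
                 p50_lat_mean = mean(g$p50_lat), p50_lat_se = se(g$p50_lat),
                 n70_lat_mean = mean(g$n70_lat), n70_lat_se = se(g$n70_lat),
                 snr_p50_mean = mean(g$snr_p50), snr_n70_mean = mean(g$snr_n70),
                 n = nrow(g))
    }))
    rownames(table2) <- NULL
    auc_tbl <- do.call(rbind, lapply(split(s1, s1$pulse_width), function(g) {
      data.frame(pulse_width = g$pulse_width[1],
                 auc_p50_mean = mean(g$auc_p50), auc_p50_se = se(g$auc_p50),
                 auc_n70_mean = mean(g$auc_n70), auc_n70_se = se(g$auc_n70))
    }))
    rownames(auc_tbl) <- NULL

    if (config$n_subjects >= 2 && length(config$pulse_widths) >= 2) {
      wide <- function(col) {
        m <- stats::reshape(s1[, c("subject", "pulse_width", col)],
                            idvar = "subject", timevar = "pulse_width",
                            direction = "wide")
        as.matrix(m[, -1, drop = FALSE])
      }
      for (meas in c("n70_amp", "p50_amp", "auc_n70", "auc_p50", "snr_n70")) {
        mat <- wide(meas)
        if (meas %in% c("n70_amp")) mat <- abs(mat) # magnitude comparison
        fr <- friedman_rm(mat)
        ph <- NULL
        if (fr$p_value < 0.05 && ncol(mat) > 2) {
          pairs <- utils::combn(ncol(mat), 2)
          praw <- apply(pairs, 2, function(ij) {
            wilcoxon_signed_rank(mat[, ij[1]], mat[, ij[2]])$p_value
          })
          ph <- data.frame(pair = apply(pairs, 2, paste, collapse = "-"),
                           p_raw = praw, p_holm = holm_adjust(praw))
        }
        stats_out[[meas]] <- list(friedman = fr, posthoc = ph)
      }
    } else {
      notes <- c(notes, "group statistics skipped: need >= 2 subjects and >= 2 conditions")
    }
  }

  table3 <- NULL
  if (config$include_eeg && config$n_sessions >= 2 && config$n_subjects >= 3) {
    s2 <- runs[runs$session == 2, , drop = FALSE]
    table3 <- do.call(rbind, lapply(config$pulse_widths, function(pw) {
      g1 <- s1[s1$pulse_width == pw, ]; g2 <- s2[s2$pulse_width == pw, ]
      common <- intersect(g1$subject, g2$subject)
      do.call(rbind, lapply(c("n70_amp", "p50_amp", "n70_lat", "p50_lat"),
                            function(meas) {
        m <- cbind(g1[match(common, g1$subject), meas],
                   g2[match(common, g2$subject), meas])
        icc <- icc_a1(m)
        data.frame(pulse_width = pw, measure = meas, icc = icc$statistic,
                   p_value = icc$p_value, ci_low = icc$ci[1],
                   ci_high = icc$ci[2], n = length(common))
      }))
    }))
    rownames(table3) <- NULL
  }

  structure(list(config = config, runs = runs, table1 = table1,
                 table2 = table2, table3 = table3, auc = auc_tbl,
                 stats = stats_out, gaps = gaps, notes = notes),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Synthetic SEP study: %d subjects x %d session(s) x %d condition(s), seed %d\n",
              x$config$n_subjects, x$config$n_sessions,
              length(x$config$pulse_widths), x$config$seed))
  if (!is.null(x$table1)) { cat("\nTarget intensities:\n"); print(x$table1, digits = 3) }
  if (!is.null(x$table2)) { cat("\nSEP components:\n"); print(x$table2, digits = 3) }
  if (!is.null(x$auc)) { cat("\nSingle-trial separability (ROC AUC):\n"); print(x$auc, digits = 3) }
  if (!is.null(x$table3)) { cat("\nTest-retest reliability (ICC(2,1)):\n"); print(x$table3, digits = 3) }
  if (length(x$stats)) {
    cat("\nRepeated-measures tests:\n")
    for (nm in names(x$stats)) {
      fr <- x$stats[[nm]]$friedman
      cat(sprintf("  %s: chi2 = %.2f, p = %.4g, w = %.2f\n",
                  nm, fr$statistic, fr$p_value, fr$effect_size))
    }
  }
  if (length(x$gaps)) cat(sprintf("\n%d subject-condition(s) skipped\n", length(x$gaps)))
  invisible(x)
}

#' Normalize target intensities by each subject's 1 ms intensity
#'
#' Per-subject division by the subject's target intensity at the 1 ms pulse
#' width, before averaging, so the 1 ms column is exactly 1. Subjects without
#' a 1 ms entry are excluded (with a message).
#'
#' @param runs Data frame with columns `subject`, `pulse_width`,
#'   `target_intensity`.
#' @param reference_pw Reference pulse width in ms (default 1).
#' @return List with `per_subject` (normalized values) and `group`
#'   (per-pulse-width mean and SE of the normalized intensity).
#' @export
normalized_intensity <- function(runs, reference_pw = 1) {
  req <- c("subject", "pulse_width", "target_intensity")
  if (!all(req %in% names(runs))) {
    stop("need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  per <- do.call(rbind, lapply(split(runs, runs$subject), function(g) {
    ref <- g$target_intensity[g$pulse_width == reference_pw]
    if (length(ref) != 1 || is.na(ref)) return(NULL)
    data.frame(subject = g$subject[1], pulse_width = g$pulse_width,
               normalized = g$target_intensity / ref)
  }))
  excluded <- setdiff(unique(runs$subject), unique(per$subject))
  if (length(excluded)) {
    message("subject(s) without a ", reference_pw, " ms entry excluded: ",
            paste(excluded, collapse = ", "))
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))
  group <- do.call(rbind, lapply(split(per, per$pulse_width), function(g) {
    data.frame(pulse_width = g$pulse_width[1],
               normalized_mean = mean(g$normalized),
               normalized_se = if (nrow(g) > 1) se(g$normalized) else NA_real_)
  }))
  rownames(group) <- NULL
  list(per_subject = per, group = group)
}

#' Write a synthetic session as delimited text
#'
#' Serializes a `synthetic_session` to a directory of tab-separated tables:
#' `eeg.tsv` (samples x channels), `events.tsv` (trial, onset sample, onset
#' seconds), and `truth.tsv` (the generator ground truth).
#'
#' @param session A `synthetic_session` from [synth_eeg_session()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eeg <- as.data.frame(t(session$eeg$data))
  names(eeg) <- session$eeg$labels
  utils::write.table(eeg, file.path(dir, "eeg.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ev <- data.frame(trial = seq_along(session$eeg$events),
                   sample = session$eeg$events,
                   onset_s = session$onsets_s)
  utils::write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(session$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- data.frame(key = c("fs", "pulse_width", "target_channel", "n70_channel"),
                     value = c(session$eeg$fs, session$pulse_width,
                               session$target_channel, session$n70_channel))
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing `eeg.tsv`, `events.tsv`, `meta.tsv` (and
#'   optionally `truth.tsv`).
#' @return A list with `eeg` ([eeg_recording]), `truth` (or NULL),
#'   `pulse_width`, `target_channel`.
#' @export
read_session <- function(dir) {
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t", header = TRUE,
                            colClasses = "character")
  fs <- as.numeric(meta$value[meta$key == "fs"])
  eeg <- utils::read.table(file.path(dir, "eeg.tsv"), sep = "\t", header = TRUE,
                           check.names = FALSE)
  ev <- utils::read.table(file.path(dir, "events.tsv"), sep = "\t", header = TRUE)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.table(truth_path, sep = "\t", header = TRUE)
  } else NULL
  list(eeg = eeg_recording(t(as.matrix(eeg)), fs, names(eeg), ev$sample),
       truth = truth,
       pulse_width = as.numeric(meta$value[meta$key == "pulse_width"]),
       target_channel = meta$value[meta$key == "target_channel"])
}
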