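#' @keywords internal
"_PACKAGE"

# Deterministic seed splitting: one master seed, fixed integer streams per
# (subject, session, condition, trial) so subject k is invariant to cohort size.
# Keeps all derived seeds strictly below 2^31 - 1.
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483629 # largest prime < 2^31
  s <- as.numeric(master) %% m
  for (i in idx) {
    s <- (s * 48271 + as.numeric(i) + 1) %% m
  }
  as.integer(s)
}

# Evaluate with a local RNG state so generators do not disturb the caller's
# random stream and are reproducible from their own seed argument.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Half-open window [start, end) in ms -> 0-based sample indices relative to the
# sample at t = t0; sample index = floor((t - t0) * fs / 1000). Returned as
# 1-based indices into an epoch whose first sample is at `epoch_start_ms`.
window_index <- function(window_ms, fs, epoch_start_ms) {
  stopifnot(length(window_ms) == 2, window_ms[1] < window_ms[2])
  first <- floor(window_ms[1] * fs / 1000)
  last <- floor(window_ms[2] * fs / 1000) - 1L
  offset <- floor(epoch_start_ms * fs / 1000)
  idx <- seq.int(first, last) - offset + 1L
  if (any(idx < 1L)) stop("window extends before epoch start", call. = FALSE)
  idx
}

# Sample times (ms) for an epoch of `n` samples starting at `start_ms`.
epoch_times <- function(n, fs, start_ms) {
  start_sample <- floor(start_ms * fs / 1000)
  (seq.int(start_sample, length.out = n)) * 1000 / fs
}

# Zero-phase (forward-backward) filtering with odd-reflection edge padding,
# so filter-state transients decay inside the pad rather than in the data.
zero_phase <- function(bf, x, pad) {
  x <- as.numeric(x)
  n <- length(x)
  p <- max(1L, min(n - 1L, as.integer(pad)))
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- as.numeric(signal::filter(bf, c(left, x, right)))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(p + 1):(p + n)]
}

stop_if_not_positive <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    if (!is.numeric(args[[i]]) || any(!is.finite(args[[i]])) || any(args[[i]] <= 0)) {
      stop(sprintf("'%s' must be a positive finite number", nm[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
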