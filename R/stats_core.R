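# Repeated-measures statistics battery: SNR, CV, Friedman + Kendall's w,
# Wilcoxon signed-rank + Holm, Lilliefors, ICC(2,1). Sample (ddof = 1)
# standard deviations are used everywhere a SD appears.

stat_result <- function(method, statistic, p_value, effect_size = NA_real_,
                        ci = c(NA_real_, NA_real_), ...) {
  out <- list(method = method, statistic = statistic, p_value = p_value,
              effect_size = effect_size, ci = ci, ...)
  class(out) <- "stat_result"
  out
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$method, x$statistic, x$p_value))
  if (!is.na(x$effect_size)) cat(sprintf(", effect size = %.3f", x$effect_size))
  if (!anyNA(x$ci)) cat(sprintf(", 95%% CI [%.3f, %.3f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Signal-to-noise ratio as mean over standard deviation
#'
#' SNR of a set of per-trial (or per-subject) response values, defined as the
#' absolute mean divided by the sample standard deviation.
#'
#' @param x Numeric vector of values (n >= 2).
#' @return Dimensionless SNR.
#' @examples
#' snr_mean_std(c(2, 4, 6)) # 2
#' @export
snr_mean_std <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("SNR undefined for zero-variance input", call. = FALSE)
  abs(mean(x)) / s
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean. A small CV (< 0.5) indicates
#' low dispersion relative to the mean.
#'
#' @param x Numeric vector with nonzero mean.
#' @return Dimensionless CV.
#' @export
coefficient_of_variation <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  stats::sd(x) / m
}

# chi-squared Friedman statistic from a matrix of within-row mid-ranks,
# with the standard tie correction.
friedman_chi2_from_ranks <- function(r) {
  n <- nrow(r); k <- ncol(r)
  Rj <- colSums(r)
  chi2 <- 12 / (n * k * (k + 1)) * sum((Rj - n * (k + 1) / 2)^2)
  # tie correction: 1 - sum over rows of sum(t^3 - t) / (n k (k^2 - 1))
  tie <- sum(vapply(seq_len(n), function(i) {
    t <- table(r[i, ])
    sum(t^3 - t)
  }, numeric(1)))
  C <- 1 - tie / (n * k * (k^2 - 1))
  if (C <= 0) return(0) # all rows fully tied
  chi2 / C
}

#' Friedman repeated-measures test
#'
#' Nonparametric test for differences across k repeated conditions measured on
#' n subjects. Values are mid-ranked within each subject; the chi-squared
#' statistic uses the standard tie correction. For small designs (n <= 5,
#' k = 3) the p-value is exact, obtained by enumerating all within-row rank
#' permutations; otherwise the chi-squared (k - 1 df) reference is used.
#'
#' @param x Numeric matrix, subjects in rows, conditions in columns. Rows with
#'   missing cells are dropped (with a message).
#' @return A `stat_result` with `statistic` (chi-squared), `p_value`,
#'   `effect_size` (Kendall's w), `n`, `k`, and whether the p was exact.
#' @seealso [kendalls_w()]
#' @export
friedman_rm <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need k >= 2 conditions", call. = FALSE)
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    message(sum(!complete), " row(s) with missing cells dropped")
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2) stop("need n >= 2 complete subjects", call. = FALSE)
  r <- t(apply(x, 1, rank))
  chi2 <- friedman_chi2_from_ranks(r)
  exact <- (n <= 5 && k == 3)
  if (exact) {
    p <- friedman_exact_p(r, chi2)
  } else {
    p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  }
  stat_result(method = if (exact) "Friedman (exact)" else "Friedman (chi-squared)",
              statistic = chi2, p_value = p,
              effect_size = kendalls_w(chi2, n, k),
              ci = c(NA_real_, NA_real_), n = n, k = k, df = k - 1, exact = exact)
}

# Exact Friedman p by enumerating, for every subject independently, all
# permutations of that subject's observed (possibly tied) rank vector.
friedman_exact_p <- function(r, chi2_obs) {
  n <- nrow(r); k <- ncol(r)
  perms <- permutations_of(k)
  # per-row matrix of the 6 (k!) permuted rank vectors
  row_opts <- lapply(seq_len(n), function(i) {
    t(apply(perms, 1, function(p) r[i, p]))
  })
  combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
  stats_all <- apply(combos, 1, function(ix) {
    rp <- do.call(rbind, lapply(seq_len(n), function(i) row_opts[[i]][ix[i], ]))
    friedman_chi2_from_ranks(rp)
  })
  mean(stats_all >= chi2_obs - 1e-10)
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  unname(out)
}

#' Kendall's coefficient of concordance from a Friedman statistic
#'
#' Effect size for the Friedman test, `w = chi2 / (n * (k - 1))`, where n is
#' the number of subjects and k the number of repeated conditions. Values are
#' clipped to the unit interval.
#'
#' @param chi2 Friedman chi-squared statistic (>= 0).
#' @param n Number of subjects (>= 1).
#' @param k Number of conditions (>= 2).
#' @return Kendall's w in `[0, 1]`.
#' @examples
#' kendalls_w(8.17, 12, 3) # 0.34 to two decimals
#' @export
kendalls_w <- function(chi2, n, k) {
  if (!is.numeric(n) || n < 1 || n != round(n)) stop("invalid n", call. = FALSE)
  if (!is.numeric(k) || k < 2 || k != round(k)) stop("invalid k", call. = FALSE)
  if (!is.numeric(chi2) || chi2 < 0) stop("chi2 must be >= 0", call. = FALSE)
  min(1, max(0, chi2 / (n * (k - 1))))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired test on `x - y`. Zero differences are dropped; absolute
#' differences are mid-ranked. For n <= 25 nonzero differences the p-value is
#' exact (distribution of the positive-rank sum over all sign patterns,
#' tie-aware); above that a normal approximation with tie-corrected variance
#' is used (no continuity correction).
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A `stat_result` with `statistic` (W+, the positive-rank sum),
#'   `p_value`, and `n` (nonzero differences used).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n < 3) stop("need at least 3 nonzero differences", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    # exact distribution of W+ over the 2^n equiprobable sign patterns,
    # computed by convolution on the doubled-rank lattice (mid-ranks are
    # multiples of 1/2)
    r2 <- as.integer(round(2 * r))
    dist <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist)
      dist <- c(dist, rep(0, ri)) + shifted
    }
    dist <- dist / sum(dist)
    w2 <- as.integer(round(2 * W))
    support <- seq_along(dist) - 1L
    p_ge <- sum(dist[support >= w2])
    p_le <- sum(dist[support <= w2])
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  stat_result(method = method, statistic = W, p_value = p, n = n)
}

#' Holm step-down multiple-comparison adjustment
#'
#' Adjusts a family of p-values by the Holm step-down procedure (sort
#' ascending, multiply the i-th smallest by m - i + 1, enforce a running
#' maximum, cap at 1), returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov distance between the empirical CDF and a normal CDF with
#' mean and SD estimated from the data, with the Lilliefors-corrected p-value.
#'
#' @param x Numeric vector (n >= 4).
#' @return A `stat_result` with `statistic` (D) and `p_value`.
#' @export
lilliefors <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("need at least 4 values", call. = FALSE)
  res <- nortest::lillie.test(x)
  stat_result(method = "Lilliefors", statistic = unname(res$statistic),
              p_value = res$p.value, n = length(x))
}

#' Intraclass correlation ICC(2,1): single measurement, absolute agreement
#'
#' Test-retest reliability from a complete subjects-by-sessions matrix, using
#' the single-measure absolute-agreement intraclass correlation from the
#' two-way ANOVA decomposition (McGraw & Wong's ICC(A,1); the same arithmetic
#' is commonly labelled ICC(2,1)):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' with the F-based 95 percent confidence interval and p-value.
#'
#' @param x Numeric matrix, n subjects (rows) by k sessions (columns),
#'   complete, n >= 3, k >= 2.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A `stat_result` with `statistic` (the ICC), `p_value`, `ci`, the
#'   mean squares, and an `interpretation` band (poor < 0.5, moderate
#'   0.5-0.75, good 0.75-0.9, excellent > 0.9).
#' @examples
#' icc_a1(matrix(c(1, 3, 5, 2, 4, 6), ncol = 2)) # 8/9
#' @export
icc_a1 <- function(x, conf_level = 0.95) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("matrix must be complete", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need n >= 3 subjects", call. = FALSE)
  if (k < 2) stop("need k >= 2 sessions", call. = FALSE)
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  SSE <- sum((x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  icc <- if (denom == 0) NA_real_ else (MSR - MSE) / denom
  # F test of H0: ICC = 0 and Satterthwaite-based CI (McGraw & Wong 1996)
  if (MSE > 0) {
    Fobs <- MSR / MSE
    p <- stats::pf(Fobs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    alpha <- 1 - conf_level
    Fc <- MSC / MSE
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * Fc + b)^2 /
      ((a^2 * Fc^2) / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lower, upper)
  } else {
    # degenerate: no residual error; agreement limited only by session effects
    p <- if (SSR > 0) 0 else NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  band <- if (is.na(icc)) NA_character_
  else if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
  stat_result(method = "ICC(2,1) absolute agreement, single measurement",
              statistic = icc, p_value = p, effect_size = icc, ci = ci,
              n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE,
              interpretation = band)
}
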