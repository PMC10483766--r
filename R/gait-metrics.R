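#' Segment gait cycles from a vertical ground-reaction-force trace
#'
#' Heel strikes are detected as upward crossings of the vertical GRF through
#' a force threshold; one gait cycle runs from heel strike to the next
#' ipsilateral heel strike.  Incomplete edge cycles (before the first and
#' after the last detected strike) are discarded.
#'
#' @param grf numeric vector, vertical ground reaction force (N) of one foot.
#' @param time numeric vector of timestamps (s); defaults to sample index.
#' @param threshold force threshold for contact (default 20 N).
#' @return list with `events` (interpolated crossing times), `cycles`
#'   (data frame with `start`, `end`, `i_start`, `i_end` sample indices) and
#'   `n_cycles`.
#' @export
segment_cycles <- function(grf, time = seq_along(grf) - 1, threshold = 20) {
  stopifnot(length(grf) == length(time), length(grf) >= 2L)
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  below <- grf < threshold
  idx <- which(below[-length(grf)] & !below[-1])   # rising through threshold
  if (length(idx) < 2L)
    stop("fewer than one complete gait cycle detected (",
         length(idx), " heel strikes)")
  # linear interpolation of the exact crossing time
  tt <- time[idx] + (threshold - grf[idx]) /
    (grf[idx + 1L] - grf[idx]) * (time[idx + 1L] - time[idx])
  n <- length(tt) - 1L
  cycles <- data.frame(start = tt[-length(tt)], end = tt[-1L],
                       i_start = idx[-length(idx)], i_end = idx[-1L] + 1L)
  list(events = tt, cycles = cycles, n_cycles = n)
}

#' Time-normalize one gait cycle to 101 points (0-100% gait cycle)
#'
#' Linear interpolation of a sampled variable onto 101 evenly spaced points
#' spanning the cycle.  An input already sampled uniformly at 101 points is
#' returned unchanged.
#'
#' @param x numeric vector of samples of one variable over one cycle.
#' @param time numeric vector of timestamps (s), strictly increasing.
#' @param n_points number of output points (default 101).
#' @return numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, time = seq_along(x), n_points = 101L) {
  stopifnot(length(x) == length(time))
  if (length(x) < 4L) stop("need at least 4 samples to normalize a cycle")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  xout <- seq(time[1L], time[length(time)], length.out = n_points)
  stats::approx(time, x, xout = xout, method = "linear", rule = 2)$y
}

#' Zero-lag cross-correlation between two gait-cycle curves
#'
#' Pearson correlation of two time-normalized 101-point curves.  The curves
#' are assumed phase-aligned by cycle normalization, so no lag search is
#' performed.
#'
#' @param sim,ref numeric vectors of equal length (simulated and reference
#'   curve).
#' @return correlation coefficient in \[-1, 1\]; `NA` (with a warning) if
#'   either curve has zero variance.
#' @export
cross_correlation <- function(sim, ref) {
  stopifnot(length(sim) == length(ref))
  if (stats::sd(sim) == 0 || stats::sd(ref) == 0) {
    warning("zero-variance curve: cross-correlation undefined")
    return(NA_real_)
  }
  stats::cor(sim, ref)
}

#' RMSE of a simulated curve in units of the reference SD
#'
#' Root-mean-square over the gait cycle of the pointwise deviation from the
#' reference mean, each point normalized by the reference standard deviation
#' at that point.  A value below 2 means the simulation lies on average
#' within the 95% band of the reference data; a curve lying exactly at
#' mean + 2 SD everywhere scores exactly 2.
#'
#' @param sim numeric vector, simulated curve (101 points).
#' @param mean numeric vector, reference mean curve; or a reference band list
#'   with elements `mean` and `sd` (see [gen_reference_band()]).
#' @param sd numeric vector, reference SD curve (ignored when `mean` is a
#'   band).
#' @return scalar RMSE in SD units.
#' @export
rmse_sd <- function(sim, mean, sd = NULL) {
  if (is.list(mean)) { sd <- mean$sd; mean <- mean$mean }
  stopifnot(length(sim) == length(mean), length(sim) == length(sd))
  if (any(sd <= 0)) stop("reference SD must be positive at every point")
  sqrt(base::mean(((sim - mean) / sd)^2))
}

# ---- one-dimensional statistical parametric mapping -------------------------

# Smoothness (FWHM, in nodes) of a residual field, Kiebel-style estimate:
# mean squared gradient of the unit-normalized residuals.
estimate_fwhm <- function(R) {
  eps <- .Machine$double.eps
  ssq <- colSums(R^2)
  dR <- t(diff(t(R)))                       # gradients along nodes
  # normalize the gradient variance by the (interpolated) field variance
  v <- colSums(dR^2) / (0.5 * (ssq[-1] + ssq[-length(ssq)]) + eps)
  v <- v[is.finite(v) & v > 0]
  if (!length(v)) return(Inf)
  sqrt(4 * log(2) / mean(v))
}

# Expected Euler characteristic of a thresholded 1D t field (random field
# theory): 0-dimensional term P(T > u) plus the 1D EC density scaled by the
# resel count.
ec_expected_t <- function(u, df, resels) {
  p0 <- stats::pt(u, df, lower.tail = FALSE)
  p1 <- resels * sqrt(4 * log(2)) / (2 * pi) *
    (1 + u^2 / df)^(-(df - 1) / 2)
  p0 + p1
}

rft_threshold_t <- function(df, resels, alpha) {
  f <- function(u) ec_expected_t(u, df, resels) - alpha
  if (f(0.1) < 0) return(0.1)   # pathologically liberal field; never in practice
  stats::uniroot(f, c(0.1, 100), tol = 1e-10)$root
}

# contiguous runs of TRUE -> cluster intervals in % gait cycle (nodes 0..Q-1)
supra_clusters <- function(supra) {
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start_pct = numeric(0), end_pct = numeric(0)))
  data.frame(start_pct = starts[keep] - 1L, end_pct = ends[keep] - 1L)
}

#' 1D statistical parametric mapping: independent two-sample t-test over the
#' gait cycle
#'
#' Computes a pointwise pooled-variance two-sample t statistic at each of the
#' 101 gait-cycle nodes and thresholds the resulting t field at the
#' alpha-level critical height from random field theory (expected Euler
#' characteristic of a smooth 1D t field, with field smoothness estimated
#' from the residual curves).  Contiguous supra-threshold runs are reported
#' as significant gait-cycle intervals.  A nonparametric cross-check is
#' available: the permutation distribution of the field maximum under group
#' exchange.
#'
#' @param A,B numeric matrices of gait cycles (rows = cycles/subjects,
#'   columns = 101 nodes), one per group.
#' @param alpha familywise significance level (default 0.05).
#' @param two_tailed test both directions (default TRUE; the threshold is set
#'   at alpha/2 per tail).
#' @param n_perm number of label permutations for the cross-check threshold;
#'   0 (default) skips the permutation pass.
#' @param seed optional seed for the permutation pass.
#' @return An object of class `"spm1d_t"`: list with `t` (t field),
#'   `df`, `fwhm`, `resels`, `threshold` (RFT critical height),
#'   `threshold_perm` (or `NA`), `clusters` (data frame of significant
#'   intervals in % gait cycle) and `excluded` (nodes with degenerate
#'   variance, reported as zero t and excluded from clusters).
#' @export
spm_ttest <- function(A, B, alpha = 0.05, two_tailed = TRUE, n_perm = 0L,
                      seed = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B), nrow(A) >= 2L, nrow(B) >= 2L)
  Q <- ncol(A); nA <- nrow(A); nB <- nrow(B)
  df <- nA + nB - 2
  t_field_of <- function(A, B) {
    mA <- colMeans(A); mB <- colMeans(B)
    sp2 <- (colSums(sweep(A, 2, mA)^2) + colSums(sweep(B, 2, mB)^2)) / df
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    tt <- (mA - mB) / se
    tt[se == 0 & (mA - mB) == 0] <- 0       # identical degenerate nodes
    list(t = tt, degenerate = se == 0)
  }
  tf <- t_field_of(A, B)
  R <- rbind(sweep(A, 2, colMeans(A)), sweep(B, 2, colMeans(B)))
  fwhm <- estimate_fwhm(R)
  resels <- (Q - 1) / fwhm
  a <- if (two_tailed) alpha / 2 else alpha
  u <- rft_threshold_t(df, resels, a)
  tt <- tf$t
  supra <- if (two_tailed) abs(tt) > u else tt > u
  supra[tf$degenerate] <- FALSE
  clusters <- supra_clusters(supra)
  thr_perm <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    pool <- rbind(A, B)
    mx <- replicate(n_perm, {
      i <- sample.int(nA + nB, nA)
      tp <- t_field_of(pool[i, , drop = FALSE], pool[-i, , drop = FALSE])$t
      if (two_tailed) max(abs(tp), na.rm = TRUE) else max(tp, na.rm = TRUE)
    })
    thr_perm <- unname(stats::quantile(mx, 1 - alpha, type = 7))
  }
  structure(list(t = tt, df = df, fwhm = fwhm, resels = resels,
                 threshold = u, threshold_perm = thr_perm,
                 clusters = clusters, excluded = which(tf$degenerate),
                 alpha = alpha, two_tailed = two_tailed),
            class = "spm1d_t")
}

#' @export
print.spm1d_t <- function(x, ...) {
  cat(sprintf(
    "SPM{t} two-sample field: df = %d, FWHM = %.1f nodes, threshold = %.3f\n",
    x$df, x$fwhm, x$threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %d-%d%% GC\n", i,
                  x$clusters$start_pct[i], x$clusters$end_pct[i]))
  }
  invisible(x)
}

#' @export
plot.spm1d_t <- function(x, ...) {
  pct <- seq(0, 100, length.out = length(x$t))
  plot(pct, x$t, type = "l", xlab = "% gait cycle", ylab = "SPM{t}", ...)
  graphics::abline(h = c(-1, 1) * x$threshold, lty = 2, col = "firebrick")
  invisible(x)
}

#' SPM z-score comparison of a single simulated curve against a reference band
#'
#' For the design where one deterministic simulation is compared against a
#' subject cohort summarised as a band, the pointwise z statistic
#' `(sim - mean) / (SD * sqrt(1 + 1/n))` forms a smooth Gaussian field;
#' the critical height comes from the 1D Gaussian EC density.
#'
#' @param sim simulated 101-point curve.
#' @param band reference band (list with `mean`, `sd`, `n`).
#' @param alpha familywise alpha (default 0.05, two-tailed).
#' @param fwhm field smoothness in nodes; estimated from the z field's
#'   gradient if `NULL`.
#' @return list with `z`, `threshold`, `clusters`.
#' @export
spm_zscore <- function(sim, band, alpha = 0.05, fwhm = NULL) {
  stopifnot(length(sim) == length(band$mean))
  n <- if (is.null(band$n)) Inf else band$n
  z <- (sim - band$mean) / (band$sd * sqrt(1 + 1 / n))
  Q <- length(z)
  if (is.null(fwhm)) {
    v <- mean(diff(z)^2) / max(mean(z^2), .Machine$double.eps)
    fwhm <- sqrt(4 * log(2) / max(v, .Machine$double.eps))
  }
  resels <- (Q - 1) / fwhm
  ec <- function(u) stats::pnorm(u, lower.tail = FALSE) +
    resels * sqrt(4 * log(2)) / (2 * pi) * exp(-u^2 / 2)
  u <- stats::uniroot(function(u) ec(u) - alpha / 2, c(0.1, 50),
                      tol = 1e-10)$root
  list(z = z, threshold = u, clusters = supra_clusters(abs(z) > u))
}

#' Validation report against reference bands
#'
#' Computes, per gait variable, the zero-lag cross-correlation with the
#' reference mean and the SD-normalized RMSE of a simulated curve against a
#' reference band.
#'
#' @param curves named list of simulated 101-point curves.
#' @param bands named list of reference bands (each with `mean` and `sd`),
#'   with names matching `curves`.
#' @return data frame with columns `variable`, `R`, `rmse_sd`.
#' @export
validation_report <- function(curves, bands) {
  vars <- intersect(names(curves), names(bands))
  if (!length(vars)) stop("no common variables between curves and bands")
  out <- lapply(vars, function(v) {
    data.frame(variable = v,
               R = cross_correlation(curves[[v]], bands[[v]]$mean),
               rmse_sd = rmse_sd(curves[[v]], bands[[v]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
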