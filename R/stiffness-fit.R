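#' Cubic least-squares fit of a gait outcome against AFO stiffness
#'
#' Fits a third-order polynomial `y = b0 + b1*K + b2*K^2 + b3*K^3` by ordinary
#' least squares.  The fit quality is summarised by the Pearson correlation
#' between fitted and observed values; a fit with `r > 0.7` is considered
#' reliable.  With four or fewer distinct stiffness values the polynomial
#' interpolates the data exactly (zero residual).
#'
#' @param K numeric vector of AFO stiffness values (Nm/degree).
#' @param y numeric vector of the response (e.g. cost of transport in J/kg/m)
#'   at each stiffness.
#' @return An object of class `"cubic_fit"`: a list with elements
#'   `coefficients` (length-4, increasing powers), `r` (Pearson correlation of
#'   fitted vs observed), `domain` (range of `K`), `K`, `y` and `fitted`.
#' @seealso [fit_optimum()], [normalization_stiffness()]
#' @export
cubic_fit <- function(K, y) {
  stopifnot(is.numeric(K), is.numeric(y), length(K) == length(y))
  ok <- is.finite(K) & is.finite(y)
  K <- K[ok]; y <- y[ok]
  if (length(K) < 2L) stop("cubic_fit needs at least 2 finite points")
  # order rows so the fit is manifestly invariant to input ordering
  o <- order(K, y)
  K <- K[o]; y <- y[o]
  fit <- stats::lm(y ~ K + I(K^2) + I(K^3))
  beta <- stats::coef(fit)
  beta[is.na(beta)] <- 0        # rank-deficient (few distinct K): drop terms
  names(beta) <- c("b0", "b1", "b2", "b3")
  yhat <- beta[1] + beta[2] * K + beta[3] * K^2 + beta[4] * K^3
  r <- if (stats::sd(y) == 0 || stats::sd(yhat) == 0) NA_real_ else
    stats::cor(yhat, y)
  structure(list(coefficients = beta, r = r, domain = range(K),
                 K = K, y = y, fitted = yhat),
            class = "cubic_fit")
}

#' @export
predict.cubic_fit <- function(object, newdata = NULL, ...) {
  K <- if (is.null(newdata)) object$K else
    if (is.list(newdata)) newdata$K else newdata
  b <- object$coefficients
  b[1] + b[2] * K + b[3] * K^2 + b[4] * K^3
}

#' @export
coef.cubic_fit <- function(object, ...) object$coefficients

#' @export
residuals.cubic_fit <- function(object, ...) object$y - object$fitted

#' @export
print.cubic_fit <- function(x, ...) {
  cat("Cubic stiffness-response fit\n")
  cat("  coefficients:", format(x$coefficients, digits = 4), "\n")
  cat(sprintf("  fit correlation r = %.4f over K in [%.3g, %.3g] (n = %d)\n",
              x$r, x$domain[1], x$domain[2], length(x$K)))
  invisible(x)
}

# Stationary points of the fitted cubic plus domain endpoints, evaluated to
# locate the minimum analytically.  Used by fit_optimum and cross-checked
# against a dense grid search in the test suite.
cubic_argmin <- function(fit) {
  b <- fit$coefficients
  lo <- fit$domain[1]; hi <- fit$domain[2]
  cand <- c(lo, hi)
  # stationary points: roots of b1 + 2 b2 K + 3 b3 K^2, computed with the
  # numerically stable quadratic form (a near-zero cubic term - e.g. exact
  # quadratic data - must not blow up the root)
  a2 <- 3 * b[4]; b2 <- 2 * b[3]; c2 <- b[2]
  if (a2 == 0) {
    if (b2 != 0) {
      r <- -c2 / b2
      if (r > lo && r < hi) cand <- c(cand, r)
    }
  } else {
    disc <- b2^2 - 4 * a2 * c2
    if (disc >= 0) {
      qq <- -(b2 + sign(b2 + (b2 == 0)) * sqrt(disc)) / 2
      r <- c(if (qq != 0) c2 / qq, qq / a2)
      cand <- c(cand, r[r > lo & r < hi])
    }
  }
  val <- predict(fit, cand)
  K_opt <- cand[which.min(val)]
  list(K_opt = K_opt, value = min(val),
       boundary = isTRUE(all.equal(K_opt, lo)) || isTRUE(all.equal(K_opt, hi)))
}

#' Energy-optimal AFO stiffness from a stiffness sweep
#'
#' Fits a third-order polynomial to cost of transport versus AFO stiffness
#' across the sweep (the no-AFO row at stiffness 0 plus the braced rows) and
#' locates its minimum on the sampled stiffness domain.  A minimum on the
#' upper domain boundary is flagged (`boundary = TRUE`), signalling that the
#' stiffness grid should be extended before trusting the optimum.  Fits with
#' correlation `r <= r_min` are marked unreliable but still reported.
#'
#' @param sweep a sweep table as returned by [run_sweep()] or
#'   [gen_sweep_table()]: a data frame with at least columns `stiffness` and
#'   the response named by `response`, and optionally a logical `ok` column
#'   flagging successful rows (failed rows are excluded from the fit).
#' @param response name of the response column; default `"cot"` (gross cost
#'   of transport, J/kg/m).
#' @param r_min minimum fit correlation regarded as reliable (default 0.7).
#' @param min_rows minimum number of successful rows required (default 5).
#' @return An object of class `"afo_optimum"` with elements `K_opt`
#'   (Nm/degree), `value` (fitted response at the optimum), `value_zero`
#'   (fitted response at stiffness 0), `reduction` (`value_zero - value`),
#'   `boundary`, `r`, `reliable` and `fit` (the underlying [cubic_fit()]).
#' @examples
#' sw <- gen_sweep_table(sweep_config(K_star = 3.8, noise_sd = 0), seed = 1)
#' opt <- fit_optimum(sw)
#' opt$K_opt
#' @export
fit_optimum <- function(sweep, response = "cot", r_min = 0.7, min_rows = 5L) {
  sweep <- as.data.frame(sweep)
  if (!all(c("stiffness", response) %in% names(sweep)))
    stop("sweep must contain columns 'stiffness' and '", response, "'")
  ok <- if ("ok" %in% names(sweep)) as.logical(sweep$ok) else
    rep(TRUE, nrow(sweep))
  ok[is.na(ok)] <- FALSE
  ok <- ok & is.finite(sweep$stiffness) & is.finite(sweep[[response]])
  if (sum(ok) < min_rows)
    stop("fit_optimum needs at least ", min_rows, " successful rows, got ",
         sum(ok))
  fit <- cubic_fit(sweep$stiffness[ok], sweep[[response]][ok])
  am <- cubic_argmin(fit)
  value_zero <- unname(predict(fit, 0))
  structure(list(K_opt = unname(am$K_opt), value = unname(am$value),
                 value_zero = value_zero,
                 reduction = value_zero - unname(am$value),
                 boundary = am$boundary, r = fit$r,
                 reliable = is.finite(fit$r) && fit$r > r_min,
                 response = response, fit = fit,
                 call = match.call()),
            class = "afo_optimum")
}

#' @export
print.afo_optimum <- function(x, digits = 3, ...) {
  cat("Optimal AFO stiffness (cubic response fit)\n")
  cat(sprintf("  K_opt     : %.*f Nm/degree%s\n", digits, x$K_opt,
              if (x$boundary) "  [boundary minimum - extend the grid]" else ""))
  cat(sprintf("  %s at optimum: %.*f;  at K = 0: %.*f;  reduction: %.*f\n",
              x$response, digits, x$value, digits, x$value_zero,
              digits, x$reduction))
  cat(sprintf("  fit r = %.3f (%s)\n", x$r,
              if (x$reliable) "reliable" else "unreliable, r <= 0.7"))
  invisible(x)
}

#' @export
summary.afo_optimum <- function(object, ...) {
  out <- c(K_opt = object$K_opt, value = object$value,
           value_zero = object$value_zero, reduction = object$reduction,
           r = object$r, boundary = as.numeric(object$boundary),
           reliable = as.numeric(object$reliable))
  class(out) <- "summary.afo_optimum"
  out
}

#' @export
print.summary.afo_optimum <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' @export
coef.afo_optimum <- function(object, ...) object$fit$coefficients

#' @export
predict.afo_optimum <- function(object, newdata = NULL, ...)
  predict(object$fit, newdata, ...)

#' @export
residuals.afo_optimum <- function(object, ...) residuals(object$fit)

#' @export
plot.afo_optimum <- function(x, ...) {
  Kd <- seq(x$fit$domain[1], x$fit$domain[2], length.out = 200)
  plot(x$fit$K, x$fit$y, xlab = "AFO stiffness (Nm/degree)",
       ylab = x$response, pch = 19, ...)
  graphics::lines(Kd, predict(x$fit, Kd), col = "steelblue", lwd = 2)
  graphics::abline(v = x$K_opt, lty = 2, col = "firebrick")
  invisible(x)
}

#' Normative gait-parameter thresholds
#'
#' Normative stance-phase targets used to define the minimum AFO stiffness
#' that normalizes each gait parameter: maximal stance ankle dorsiflexion
#' 17.2 degrees, minimal stance knee flexion 4.2 degrees, external knee
#' extension moment bound 0.34 Nm/kg, and peak ankle moment target
#' 1.17 Nm/kg (normative mean minus 2 SD; the ankle moment levels off below
#' the normative mean even at high stiffness).  The `direction` states which
#' way the cubic fit must cross the threshold for the parameter to count as
#' normalized: `"decrease"` (pathological value above, normal at or below)
#' or `"increase"` (pathological below, normal at or above).
#'
#' @return data frame with columns `parameter`, `column`, `threshold`,
#'   `direction`.
#' @export
normative_thresholds <- function() {
  data.frame(
    parameter = c("ankle_angle", "ankle_moment", "knee_angle", "knee_moment"),
    column    = c("ankle_angle_max", "ankle_moment_max",
                  "knee_angle_min", "knee_moment_min"),
    threshold = c(17.2, 1.17, 4.2, 0.34),
    direction = c("decrease", "increase", "decrease", "increase"),
    stringsAsFactors = FALSE
  )
}

#' Minimum AFO stiffness normalizing each gait parameter
#'
#' For each gait parameter, fits a third-order polynomial against AFO
#' stiffness and finds the smallest stiffness `K >= 0` at which the fit
#' crosses the normative threshold in the normalizing direction.  A
#' parameter already on the normal side of its threshold at `K = 0` needs no
#' orthosis (`K_norm = 0`); a fit that never reaches the threshold on the
#' sampled domain yields `NA` with `crossed = FALSE`.
#'
#' @inheritParams fit_optimum
#' @param thresholds data frame in the format of [normative_thresholds()].
#' @param tol absolute root-finding tolerance on K (default 1e-8 Nm/degree).
#' @return data frame with one row per parameter: `parameter`, `K_norm`,
#'   `crossed`, `at_zero` (fitted value at K = 0), `r`, `reliable`.
#' @export
normalization_stiffness <- function(sweep, thresholds = normative_thresholds(),
                                    r_min = 0.7, min_rows = 5L, tol = 1e-8) {
  sweep <- as.data.frame(sweep)
  ok <- if ("ok" %in% names(sweep)) as.logical(sweep$ok) else
    rep(TRUE, nrow(sweep))
  ok[is.na(ok)] <- FALSE
  out <- lapply(seq_len(nrow(thresholds)), function(i) {
    col <- thresholds$column[i]
    thr <- thresholds$threshold[i]
    dirn <- thresholds$direction[i]
    if (!col %in% names(sweep))
      stop("sweep lacks column '", col, "'")
    use <- ok & is.finite(sweep$stiffness) & is.finite(sweep[[col]])
    if (sum(use) < min_rows)
      stop("normalization_stiffness needs at least ", min_rows,
           " successful rows for ", col)
    fit <- cubic_fit(sweep$stiffness[use], sweep[[col]][use])
    # signed distance from normal: positive while still pathological
    g <- function(K) {
      v <- predict(fit, K)
      if (dirn == "decrease") v - thr else thr - v
    }
    lo <- max(0, fit$domain[1]); hi <- fit$domain[2]
    at_zero <- unname(predict(fit, lo))
    K_norm <- NA_real_; crossed <- FALSE
    if (g(lo) <= 0) {                     # already normalized without AFO
      K_norm <- 0; crossed <- TRUE
    } else {
      # smallest sign change on a dense scan, refined by uniroot
      Ks <- seq(lo, hi, length.out = 512L)
      gs <- g(Ks)
      j <- which(gs[-1] <= 0 & gs[-length(gs)] > 0)
      if (length(j)) {
        j <- j[1]
        root <- stats::uniroot(g, c(Ks[j], Ks[j + 1]), tol = tol)
        K_norm <- root$root; crossed <- TRUE
      }
    }
    data.frame(parameter = thresholds$parameter[i], K_norm = K_norm,
               crossed = crossed, at_zero = at_zero, r = fit$r,
               reliable = is.finite(fit$r) && fit$r > r_min,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare energy-optimal and normalizing AFO stiffnesses across models
#'
#' Each simulated musculoskeletal model contributes one energy-optimal
#' stiffness and one normalizing stiffness; models are treated as individual
#' subjects and the two sets are compared with an independent two-sample
#' t-test (pooled variance), alongside the per-model paired differences.
#'
#' @param K_opt numeric vector of energy-optimal stiffnesses, one per model.
#' @param K_norm numeric vector of normalizing stiffnesses, same order.
#' @return list with `mean_diff`, `sd_diff` (of the per-model differences),
#'   `t`, `df`, `p_value`, `n`.
#' @export
compare_optima <- function(K_opt, K_norm) {
  stopifnot(length(K_opt) == length(K_norm))
  keep <- is.finite(K_opt) & is.finite(K_norm)
  x <- K_opt[keep]; y <- K_norm[keep]
  n <- length(x)
  if (n < 2L) stop("compare_optima needs at least 2 models")
  d <- x - y
  sp2 <- ((n - 1) * stats::var(x) + (n - 1) * stats::var(y)) / (2 * n - 2)
  md <- mean(x) - mean(y)
  if (sp2 <= 0) {                          # degenerate variance
    tstat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    tstat <- md / sqrt(sp2 * (2 / n))
    p <- 2 * stats::pt(-abs(tstat), df = 2 * n - 2)
  }
  list(mean_diff = mean(d), sd_diff = stats::sd(d),
       t = tstat, df = 2 * n - 2, p_value = p, n = n)
}
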