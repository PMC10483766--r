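# Covariance Matrix Adaptation Evolution Strategy, standard (mu/mu_w, lambda)
# formulation with rank-one and rank-mu covariance updates and cumulative
# step-size adaptation.  Box constraints are handled by projecting sampled
# candidates onto the feasible box before evaluation.

#' Minimize a function with CMA-ES
#'
#' Derivative-free stochastic minimization.  The search runs in coordinates
#' normalized by the box width, so heterogeneous parameter scales are
#' handled automatically.  Termination: a hard generation cap, and the
#' plateau rule that stops when the mean per-generation improvement of the
#' best cost, averaged over a trailing window, drops below a relative
#' threshold.
#'
#' @param fn objective function taking a numeric vector.
#' @param x0 initial point (length n).
#' @param lower,upper box constraints (length n, finite).
#' @param sigma0 initial step size in box-width units (default 0.25).
#' @param lambda population size; default `4 + floor(3 log n)`.
#' @param max_gen generation cap (default 2000).
#' @param window plateau window in generations (default 500).
#' @param improve_tol relative improvement per generation below which the
#'   plateau rule fires (default 1e-5, i.e. 0.001%).
#' @param seed RNG seed: the run is fully reproducible given it.
#' @param trace_every record the best/mean cost every this many generations.
#' @param progress_fn optional callback invoked every `trace_every`
#'   generations with `(generation, f_best, x_best)` — e.g. to checkpoint
#'   long optimizations to disk.
#' @return list with `x_best`, `f_best`, `n_eval`, `generations`,
#'   `converged` (plateau rule fired before the cap) and `trace`
#'   (data frame: generation, f_best, f_mean).
#' @export
cmaes_minimize <- function(fn, x0, lower, upper, sigma0 = 0.25,
                           lambda = NULL, max_gen = 2000L, window = 500L,
                           improve_tol = 1e-5, seed = 1L,
                           trace_every = 10L, progress_fn = NULL) {
  n <- length(x0)
  stopifnot(length(lower) == n, length(upper) == n, all(upper > lower),
            all(x0 >= lower), all(x0 <= upper))
  set.seed(seed)
  scale <- upper - lower
  to_unit <- function(x) (x - lower) / scale
  from_unit <- function(z) lower + z * scale

  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- to_unit(x0)
  sigma <- sigma0
  C <- diag(n); pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n)
  eigen_stale <- 0

  # seed the incumbent with the starting point so a warm start can never
  # be lost to a worse early sample
  f_best <- fn(x0); x_best <- x0; n_eval <- 1L
  best_hist <- numeric(0)
  tr_gen <- tr_best <- tr_mean <- numeric(0)
  converged <- FALSE
  gen <- 0L

  while (gen < max_gen) {
    gen <- gen + 1L
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                     # N(0, C) samples
    X <- m + sigma * Y
    Xc <- pmin(pmax(X, 0), 1)              # project onto the unit box
    f <- apply(Xc, 2, function(z) fn(from_unit(z)))
    n_eval <- n_eval + lambda
    ord <- order(f)
    if (f[ord[1]] < f_best) {
      f_best <- f[ord[1]]
      x_best <- from_unit(Xc[, ord[1]])
    }
    best_hist <- c(best_hist, f_best)

    sel <- ord[seq_len(mu)]
    ysel <- (Xc[, sel, drop = FALSE] - m) / sigma
    yw <- as.numeric(ysel %*% w)
    m <- m + sigma * yw

    # step-size path (C^{-1/2} y_w)
    Cinvsqrt_y <- B %*% ((1 / D) * crossprod(B, yw))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * Cinvsqrt_y
    hsig <- as.numeric(
      sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
        1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * (ysel %*% (w * t(ysel)))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 2)

    eigen_stale <- eigen_stale + 1
    if (eigen_stale >= max(1, floor(1 / (10 * n * (c1 + cmu))))) {
      eigen_stale <- 0
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eg$values, 1e-20))
      B <- eg$vectors
    }

    if (gen %% trace_every == 0 || gen == 1L) {
      tr_gen <- c(tr_gen, gen); tr_best <- c(tr_best, f_best)
      tr_mean <- c(tr_mean, mean(f))
      if (!is.null(progress_fn)) progress_fn(gen, f_best, x_best)
    }

    # plateau rule: mean improvement over the trailing window below
    # improve_tol (relative) per generation
    if (gen > window) {
      then <- best_hist[gen - window]
      rel <- (then - f_best) / max(abs(then), 1e-12) / window
      if (rel < improve_tol) { converged <- TRUE; break }
    }
  }

  list(x_best = x_best, f_best = f_best, n_eval = n_eval,
       generations = gen, converged = converged,
       trace = data.frame(generation = tr_gen, f_best = tr_best,
                          f_mean = tr_mean))
}
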