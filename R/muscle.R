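#' Normalized Hill-type muscle curves
#'
#' The four normalized curves of the equilibrium muscle model: active
#' force-length (Gaussian, peak 1 at optimal length), passive fiber
#' force-length (exponential, zero at and below optimal length), tendon
#' force-strain (exponential toe, force 1 at the isometric strain) and
#' force-velocity (hyperbolic shortening limb reaching 0 at the maximal
#' shortening velocity, saturating eccentric limb).
#'
#' @param x normalized fiber length (`active_fl`, `passive_fl`), tendon
#'   strain (`tendon_fl`) or normalized fiber velocity, shortening negative
#'   (`fv`).
#' @param which curve name.
#' @param model optional `afo_model` supplying the curve constants; the
#'   packaged defaults are used if omitted.
#' @return numeric vector of normalized force multipliers.
#' @export
hill_curves <- function(x, which = c("active_fl", "passive_fl", "tendon_fl",
                                     "fv"), model = NULL) {
  which <- match.arg(which)
  cc <- curve_constants(model)
  cpp_hill_curves(as.numeric(x), which, cc)
}

curve_constants <- function(model = NULL) {
  cv <- if (is.null(model)) {
    list(fl_width = 0.45, kpe = 4.0, e0 = 0.6, eps_iso = 0.049, kten = 3.0,
         fvmax = 1.4, af = 0.25, damping = 0.1)
  } else model$curves
  unlist(cv[c("fl_width", "kpe", "e0", "eps_iso", "kten", "fvmax", "af",
              "damping")])
}

#' First-order muscle activation dynamics
#'
#' Exact one-step update of `da/dt = (u - a)/tau`, with a faster time
#' constant during activation (`u > a`) than deactivation.  Both excitation
#' and activation are clipped to `[0, 1]`.
#'
#' @param u neural excitation in `[0, 1]`.
#' @param a current activation in `[0, 1]`.
#' @param dt step (s).
#' @param tau_act,tau_deact activation / deactivation time constants (s).
#' @return updated activation, vectorized over `u`/`a`.
#' @export
activation_dynamics <- function(u, a, dt, tau_act = 0.01, tau_deact = 0.04) {
  n <- max(length(u), length(a))
  u <- rep_len(u, n); a <- rep_len(a, n)
  vapply(seq_len(n), function(i)
    cpp_activation_update(u[i], a[i], dt, tau_act, tau_deact), 0)
}

#' Solve the muscle-tendon static equilibrium
#'
#' Finds the normalized fiber length at which the isometric fiber force
#' (active plus passive, projected through the pennation angle) balances the
#' tendon force for a given musculotendon path length and activation.
#' Solved by bisection on the monotone force balance to a relative tolerance
#' of 1e-8; with `rigid_tendon = TRUE` the tendon is inextensible at its
#' slack length and the fiber length follows directly from the geometry.
#'
#' @param params list with muscle parameters `fmax`, `lopt`, `lslack`,
#'   `penn` (rad) and optionally `fpas_scale`, `ften_scale` (default 1).
#' @param lmt musculotendon path length (m).
#' @param activation activation in `[0, 1]`.
#' @param model optional `afo_model` for the curve constants.
#' @param rigid_tendon treat the tendon as inextensible.
#' @param tol relative force-balance tolerance.
#' @return list of class `"muscle_state"`: `activation`, `lm_norm`
#'   (normalized fiber length), `fiber_velocity` (0, static), `tendon_force`
#'   (N), `cos_penn`, `converged`, `residual`.
#' @export
solve_equilibrium <- function(params, lmt, activation, model = NULL,
                              rigid_tendon = FALSE, tol = 1e-8) {
  stopifnot(activation >= 0, activation <= 1, lmt > 0)
  cc <- curve_constants(model)
  fpas <- if (is.null(params$fpas_scale)) 1 else params$fpas_scale
  ften <- if (is.null(params$ften_scale)) 1 else params$ften_scale
  h <- params$lopt * sin(params$penn)
  cosp <- function(ln) {
    s <- h / pmax(ln * params$lopt, h + 1e-9)
    sqrt(pmax(1 - s^2, 1e-9))
  }
  fiber_iso <- function(ln)
    (activation * cpp_hill_curves(ln, "active_fl", cc) +
       fpas * cpp_hill_curves(ln, "passive_fl", cc)) * cosp(ln)
  tendon <- function(ln) {
    lt <- lmt - ln * params$lopt * cosp(ln)
    ften * cpp_hill_curves(lt / params$lslack - 1, "tendon_fl", cc)
  }
  if (rigid_tendon) {
    # inextensible tendon at slack length
    f <- function(ln) ln * params$lopt * cosp(ln) - (lmt - params$lslack)
    ln <- stats::uniroot(f, c(1e-3, 3), tol = 1e-12)$root
    ft <- fiber_iso(ln) * params$fmax
    return(structure(list(activation = activation, lm_norm = ln,
                          fiber_velocity = 0, tendon_force = ft,
                          cos_penn = cosp(ln), converged = TRUE,
                          residual = 0), class = "muscle_state"))
  }
  bal <- function(ln) fiber_iso(ln) - tendon(ln)   # increasing in ln
  lo <- 0.05; hi <- 2.5
  if (bal(lo) > 0 || bal(hi) < 0) {
    # degenerate geometry: no balance within physiologic fiber lengths
    ln <- if (bal(lo) > 0) lo else hi
    return(structure(list(activation = activation, lm_norm = ln,
                          fiber_velocity = 0,
                          tendon_force = tendon(ln) * params$fmax,
                          cos_penn = cosp(ln), converged = FALSE,
                          residual = bal(ln)), class = "muscle_state"))
  }
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (bal(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-14) break
  }
  ln <- 0.5 * (lo + hi)
  scale <- max(abs(tendon(ln)), abs(fiber_iso(ln)), 1e-12)
  res <- abs(bal(ln)) / scale
  structure(list(activation = activation, lm_norm = ln, fiber_velocity = 0,
                 tendon_force = tendon(ln) * params$fmax,
                 cos_penn = cosp(ln), converged = res < tol,
                 residual = res), class = "muscle_state")
}

#' @export
print.muscle_state <- function(x, ...) {
  cat(sprintf(
    "muscle state: a = %.3f, lm = %.4f lopt, F_tendon = %.1f N (%s)\n",
    x$activation, x$lm_norm, x$tendon_force,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Musculotendon path lengths at a posture
#'
#' @param model an `afo_model`.
#' @param q generalized positions (rad, m).
#' @param muscles optional character vector of muscle names (with `_r`/`_l`
#'   suffix); all 18 by default.
#' @return named numeric vector of path lengths (m).
#' @export
muscle_length <- function(model, q, muscles = NULL) {
  cm <- compile_model(model)
  L <- cpp_muscle_lengths(cm, as.numeric(q))
  names(L) <- cm$muscle_names
  if (!is.null(muscles)) L <- L[muscles]
  L
}

#' Muscle moment arm about a generalized coordinate
#'
#' Central finite difference of the musculotendon path length with respect
#' to the joint angle: `r = -dL/dq`, positive when the muscle's shortening
#' drives the coordinate in its positive direction.
#'
#' @param model an `afo_model`.
#' @param q posture.
#' @param muscle muscle name with leg suffix (e.g. `"soleus_r"`).
#' @param coord coordinate name (see [coord_names()]).
#' @param h finite-difference step (rad).
#' @return moment arm (m).
#' @export
moment_arm <- function(model, q, muscle, coord, h = 1e-5) {
  j <- match(coord, coord_names())
  qp <- q; qp[j] <- qp[j] + h
  qm <- q; qm[j] <- qm[j] - h
  Lp <- muscle_length(model, qp, muscle)
  Lm <- muscle_length(model, qm, muscle)
  unname(-(Lp - Lm) / (2 * h))
}
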