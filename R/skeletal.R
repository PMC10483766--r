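#' Knee ligament torque
#'
#' Rotational spring (2 Nm/degree) and damper (0.2 Nm/degree/s) engaging
#' when the knee flexes beyond 120 degrees or extends beyond 10 degrees of
#' flexion; inside the open interval (10, 120) degrees the torque is exactly
#' zero.  The damper acts only while the spring is engaged.  Torque is
#' signed to resist further excursion: positive toward flexion.
#'
#' @param angle knee flexion angle in degrees (0 = full extension).
#' @param angvel knee angular velocity in degrees/s (flexion positive).
#' @param k spring constant, Nm/degree.
#' @param c damping constant, Nm/degree/s.
#' @param flex_limit,ext_limit engagement limits in degrees of flexion.
#' @return torque in Nm, vectorized over `angle`/`angvel`.
#' @export
knee_ligament_torque <- function(angle, angvel = 0, k = 2, c = 0.2,
                                 flex_limit = 120, ext_limit = 10) {
  n <- max(length(angle), length(angvel))
  angle <- rep_len(angle, n); angvel <- rep_len(angvel, n)
  vapply(seq_len(n), function(i)
    cpp_knee_ligament_torque(angle[i], angvel[i], k, c, flex_limit,
                             ext_limit), 0)
}

#' AFO torsional spring torque
#'
#' Linear torsional spring around the ankle with a neutral angle of zero
#' degrees: plantarflexing when the ankle is dorsiflexed and dorsiflexing
#' when plantarflexed.  A stiffness of 0 reproduces the no-AFO model exactly.
#'
#' @param ankle_angle ankle angle in degrees (dorsiflexion positive).
#' @param K_afo stiffness in Nm/degree, must be >= 0.
#' @return torque in Nm (dorsiflexion positive), vectorized.
#' @export
afo_torque <- function(ankle_angle, K_afo) {
  if (any(K_afo < 0)) stop("AFO stiffness must be >= 0")
  n <- max(length(ankle_angle), length(K_afo))
  ankle_angle <- rep_len(ankle_angle, n); K_afo <- rep_len(K_afo, n)
  vapply(seq_len(n), function(i)
    cpp_afo_torque(ankle_angle[i], K_afo[i]), 0)
}

#' Model state constructor
#'
#' @param q generalized positions: pelvis x, y (m), pelvis tilt and six
#'   joint angles (rad).
#' @param qd generalized velocities.
#' @param time simulation time (s).
#' @return list of class `"model_state"`.
#' @export
model_state <- function(q = rep(0, 9), qd = rep(0, 9), time = 0) {
  stopifnot(length(q) == 9, length(qd) == 9, all(is.finite(c(q, qd))))
  structure(list(q = as.numeric(q), qd = as.numeric(qd), time = time),
            class = "model_state")
}

#' Advance the planar equations of motion one step
#'
#' One fixed step of the semi-implicit (symplectic) Euler scheme on the
#' 9-DOF equations of motion, with arbitrary applied generalized forces and
#' external point forces.  Deterministic given its inputs; a diverging
#' (non-finite) state is signalled as an error so the caller can apply the
#' falling penalty.
#'
#' @param model an `afo_model`.
#' @param state a [model_state()].
#' @param dt step size (s), > 0.
#' @param tau generalized applied forces (length 9: pelvis Fx, Fy, torque,
#'   then joint torques in Nm).
#' @param ext_forces optional matrix of external point forces, one row per
#'   force: `(segment index 1-7, local x, local y, Fx, Fy)`.
#' @return the advanced `model_state`.
#' @export
forward_dynamics_step <- function(model, state, dt, tau = rep(0, 9),
                                  ext_forces = NULL) {
  stopifnot(inherits(state, "model_state"), dt > 0, length(tau) == 9)
  cm <- compile_model(model)
  ef <- if (is.null(ext_forces)) NULL else {
    ef <- as.matrix(ext_forces)
    ef[, 1] <- ef[, 1] - 1   # 0-based segment index for the engine
    ef
  }
  d <- cpp_dynamics(cm, state$q, state$qd, as.numeric(tau), ef)
  qd <- state$qd + dt * d$qdd
  q <- state$q + dt * qd
  if (!all(is.finite(q)) || !all(is.finite(qd)))
    stop("forward dynamics diverged (non-finite state)")
  model_state(q, qd, state$time + dt)
}

#' Passive simulation (no muscles, optional contact) for mechanics audits
#'
#' Integrates the unactuated skeleton from an arbitrary initial state,
#' either with the engine's fixed-step semi-implicit scheme or with an
#' error-controlled reference integrator (`deSolve::ode`, LSODA) for energy
#' audits.
#'
#' @param model an `afo_model`.
#' @param state initial [model_state()].
#' @param duration simulated time (s).
#' @param dt fixed step (s) / output resolution for the reference method.
#' @param contact include foot-ground contact (default FALSE).
#' @param method `"fixed"` (engine) or `"reference"` (error-controlled).
#' @param K_afo AFO stiffness Nm/degree (default 0).
#' @return list with `time`, `q`, `qd` matrices (rows = samples).
#' @export
simulate_passive <- function(model, state, duration, dt = 1e-4,
                             contact = FALSE,
                             method = c("fixed", "reference"), K_afo = 0) {
  method <- match.arg(method)
  cm <- compile_model(model)
  if (method == "fixed") {
    opt <- engine_options(duration = duration, dt = dt, record_dt = dt,
                          K_afo = K_afo, use_muscles = FALSE,
                          use_contact = contact, use_controller = FALSE,
                          init_q = state$q, init_qd = state$qd,
                          settle_y = FALSE, transient = Inf)
    sim <- cpp_simulate(cm, controller_vector(model), opt)
    list(time = sim$traj$time, q = sim$traj$q, qd = sim$traj$qd)
  } else {
    deriv <- function(t, y, parms) {
      q <- y[1:9]; qd <- y[10:18]
      tau <- rep(0, 9)
      for (leg in 1:2) {
        kq <- cm$knee_q[leg] + 1L; aq <- cm$ankle_q[leg] + 1L
        tau[kq] <- tau[kq] +
          cpp_knee_ligament_torque(q[kq] * 180 / pi, qd[kq] * 180 / pi,
                                   cm$ligament[1], cm$ligament[2],
                                   cm$ligament[3], cm$ligament[4])
        tau[aq] <- tau[aq] + cpp_afo_torque(q[aq] * 180 / pi, K_afo)
      }
      d <- cpp_dynamics(cm, q, qd, tau, NULL)
      list(c(qd, d$qdd))
    }
    times <- seq(0, duration, by = dt * 10)
    out <- deSolve::ode(c(state$q, state$qd), times, deriv, NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-10)
    list(time = out[, 1], q = out[, 2:10, drop = FALSE],
         qd = out[, 11:19, drop = FALSE])
  }
}

#' @rdname simulate_passive
#' @param lock 1-based generalized-coordinate indices held fixed (their
#'   velocities are zeroed each step), e.g. everything but one hip for the
#'   compound-pendulum audit.
#' @param record_dt output sampling interval (s).
#' @export
simulate_passive_locked <- function(model, state, duration, dt = 1e-4,
                                    lock = integer(), contact = FALSE,
                                    record_dt = 1e-3) {
  cm <- compile_model(model)
  opt <- engine_options(duration = duration, dt = dt,
                        record_dt = record_dt, use_muscles = FALSE,
                        use_contact = contact, use_controller = FALSE,
                        lock = lock, init_q = state$q, init_qd = state$qd,
                        settle_y = FALSE, transient = Inf)
  sim <- cpp_simulate(cm, controller_vector(model), opt)
  list(time = sim$traj$time, q = sim$traj$q, qd = sim$traj$qd)
}

# default engine option list; shared by the simulation wrappers
engine_options <- function(duration = 10, dt = 1e-4, record_dt = 0.005,
                           K_afo = 0, transient = 2, fall_frac = 0.8,
                           use_muscles = TRUE, use_contact = TRUE,
                           use_controller = TRUE, use_gravity = TRUE,
                           act_threshold = 0.5, lock = NULL,
                           init_q = NULL, init_qd = NULL, settle_y = TRUE,
                           init_act = 0.02) {
  list(duration = duration, dt = dt, record_dt = record_dt, K_afo = K_afo,
       transient = transient, fall_frac = fall_frac,
       use_muscles = use_muscles, use_contact = use_contact,
       use_controller = use_controller, use_gravity = use_gravity,
       act_threshold = act_threshold,
       lock = if (is.null(lock)) NULL else as.integer(lock - 1L),
       init_q = init_q, init_qd = init_qd, settle_y = settle_y,
       init_act = init_act)
}
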