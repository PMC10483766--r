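#' Gait phases of the reflex controller
#'
#' Five phases per leg, advancing cyclically: early stance, late stance,
#' liftoff, swing, landing.  Stance phases require foot load; swing phases
#' require none.
#'
#' @return character vector of the phase names in cycle order.
#' @export
gait_phases <- function() phase_names()

#' Gait-phase transition
#'
#' Deterministic phase update given the leg's state and the optimized
#' transition thresholds.  Transitions: landing -> early stance when the
#' foot load rises above `load_on`; early -> late stance when the ankle has
#' passed behind the pelvis by `d_ls`; late stance -> liftoff when the
#' contralateral foot loads (double support); liftoff -> swing when the foot
#' unloads below `load_off`; swing -> landing when the swinging ankle is
#' `d_la` ahead of the pelvis, or immediately on early foot contact (load
#' above `load_on`) so a loaded leg can never sit in a swing phase.
#' Distinct on/off load thresholds provide
#' hysteresis against chattering.
#'
#' @param phase current phase (name or index 1-5).
#' @param load ipsilateral vertical foot load (body weights).
#' @param contra_load contralateral foot load (body weights).
#' @param ankle_dx sagittal ankle-to-pelvis distance (m, positive ahead).
#' @param thresholds named vector/list with `load_on`, `load_off`, `d_ls`,
#'   `d_la`.
#' @return the next phase name.
#' @export
detect_phase <- function(phase, load, contra_load, ankle_dx, thresholds) {
  ph <- phase_names()
  p <- if (is.character(phase)) match(phase, ph) else as.integer(phase)
  if (is.na(p) || p < 1 || p > 5) stop("unknown phase: ", phase)
  th <- as.list(thresholds)
  nxt <- cpp_phase_next(p - 1L, load, contra_load, ankle_dx,
                        th$load_on, th$load_off, th$d_ls, th$d_la)
  ph[nxt + 1L]
}

#' Reflex-controller muscle excitations
#'
#' Computes the 18 muscle excitations from (delayed) normalized muscle
#' force and fiber-length signals, the per-leg gait phases, and the trunk
#' state: per phase, each muscle receives its constant excitation plus
#' force-feedback (`gain * F_norm(source)`) and length-feedback
#' (`gain * max(0, l_norm(source) - l0)`) contributions; the hip muscles
#' additionally receive the proportional-derivative trunk-stabilization
#' term during stance.  The summed excitation is clipped to `[0, 1]`.
#' Pure function of its inputs: identical inputs give bit-identical output.
#'
#' @param model an `afo_model`.
#' @param params controller parameter vector (see [controller_vector()]).
#' @param phase_r,phase_l gait phase of the right / left leg (name or index).
#' @param F_norm,l_norm length-18 vectors of delayed normalized tendon
#'   forces and fiber lengths (right-leg muscles 1-9, left 10-18).
#' @param trunk_pitch,trunk_pitch_vel pelvis tilt (rad) and velocity (rad/s).
#' @return named numeric vector of 18 excitations in `[0, 1]`.
#' @export
muscle_excitations <- function(model, params, phase_r, phase_l,
                               F_norm = rep(0, 18), l_norm = rep(1, 18),
                               trunk_pitch = 0, trunk_pitch_vel = 0) {
  ph <- phase_names()
  pr <- if (is.character(phase_r)) match(phase_r, ph) else as.integer(phase_r)
  pl <- if (is.character(phase_l)) match(phase_l, ph) else as.integer(phase_l)
  stopifnot(!is.na(pr), !is.na(pl), length(F_norm) == 18,
            length(l_norm) == 18)
  cm <- compile_model(model)
  u <- cpp_excitations(cm, as.numeric(params), pr - 1L, pl - 1L,
                       as.numeric(F_norm), as.numeric(l_norm),
                       trunk_pitch, trunk_pitch_vel)
  stats::setNames(u, cm$muscle_names)
}
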