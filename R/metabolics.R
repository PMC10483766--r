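#' Whole-body muscle metabolic rate
#'
#' Muscle energetics of the standard activation/maintenance +
#' shortening-heat + mechanical-work form: per muscle,
#' `rate = m * a * (A + M * f_L(l)) + S * F * max(0, -v) + max(0, -F * v)`
#' with muscle mass `m = F_max * l_opt * rho / sigma`, clamped at zero, plus
#' a basal rate proportional to body mass.  The rate is non-negative and,
#' at fixed kinematics, increases monotonically with activation.
#'
#' @param model an `afo_model` (supplies the coefficients and muscle
#'   parameters).
#' @param activation length-18 vector of activations in `[0, 1]`.
#' @param lm_norm normalized fiber lengths (default 1).
#' @param fiber_vel fiber velocities in m/s, shortening negative (default 0,
#'   isometric).
#' @param fiber_force fiber forces in N (default: isometric force at the
#'   given state).
#' @return list with `total` (W, including basal) and `per_muscle` (W).
#' @export
metabolic_rate <- function(model, activation, lm_norm = rep(1, 18),
                           fiber_vel = rep(0, 18), fiber_force = NULL) {
  cm <- compile_model(model)
  nm <- length(cm$m_fmax)
  stopifnot(length(activation) == nm)
  activation <- pmin(1, pmax(0, activation))
  cc <- curve_constants(model)
  met <- cm$metab
  if (is.null(fiber_force))
    fiber_force <- cm$m_fmax *
      (activation * cpp_hill_curves(lm_norm, "active_fl", cc) +
         cm$m_fpas * cpp_hill_curves(lm_norm, "passive_fl", cc))
  mmass <- cm$m_fmax * cm$m_lopt * met[["density"]] /
    met[["specific_tension"]]
  h_am <- mmass * activation *
    (met[["act_coef"]] +
       met[["maint_coef"]] * cpp_hill_curves(lm_norm, "active_fl", cc))
  h_sl <- met[["short_coef"]] * fiber_force * pmax(0, -fiber_vel)
  w <- pmax(0, -fiber_force * fiber_vel)
  per <- pmax(0, h_am + h_sl + w)
  names(per) <- cm$muscle_names
  list(total = met[["basal"]] * cm$body_mass + sum(per), per_muscle = per)
}

#' Gross cost of transport
#'
#' Total metabolic energy over the steady-state analysis window divided by
#' body mass and distance walked: J/kg/m.
#'
#' @param energy metabolic energy over the window (J).
#' @param body_mass body mass (kg).
#' @param distance distance walked over the window (m); must be positive.
#' @return cost of transport (J/kg/m).
#' @export
cost_of_transport <- function(energy, body_mass, distance) {
  if (!is.finite(distance) || distance <= 0)
    stop("failed walk: non-positive distance over the analysis window")
  stopifnot(body_mass > 0)
  energy / (body_mass * distance)
}
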