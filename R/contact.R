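#' Hunt-Crossley foot-ground contact force
#'
#' Viscoelastic normal force `k * depth^n * (1 + c * depth_rate)`, floored
#' at zero (the ground never pulls), with a velocity-regularized Coulomb
#' friction force bounded by `mu` times the normal force.  Zero force above
#' the ground.
#'
#' @param depth penetration depth (m); <= 0 means no contact.
#' @param depth_rate penetration rate (m/s, positive while penetrating
#'   deeper).
#' @param tangential_vel sliding velocity (m/s).
#' @param model optional `afo_model` supplying the contact constants.
#' @param stiffness,exponent,dissipation,friction,v_reg contact constants
#'   (used when no model is given): stiffness N/m^n, Hertz-like exponent,
#'   dissipation s/m, friction coefficient, regularization velocity m/s.
#' @return named vector with `normal` and `tangential` force components (N),
#'   or a two-column matrix for vector input.
#' @export
contact_force <- function(depth, depth_rate = 0, tangential_vel = 0,
                          model = NULL, stiffness = 12e6, exponent = 1.5,
                          dissipation = 1.0, friction = 0.9, v_reg = 0.05) {
  if (!is.null(model)) {
    ct <- model$contact
    stiffness <- ct$stiffness; exponent <- ct$exponent
    dissipation <- ct$dissipation; friction <- ct$friction
    v_reg <- ct$v_reg
  }
  n <- max(length(depth), length(depth_rate), length(tangential_vel))
  depth <- rep_len(depth, n); depth_rate <- rep_len(depth_rate, n)
  tangential_vel <- rep_len(tangential_vel, n)
  out <- t(vapply(seq_len(n), function(i)
    cpp_contact_force(depth[i], depth_rate[i], tangential_vel[i],
                      stiffness, exponent, dissipation, friction, v_reg),
    c(normal = 0, tangential = 0)))
  if (n == 1L) out[1, ] else out
}
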