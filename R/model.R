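#' Read a planar walking-model configuration
#'
#' Loads the structured-text (YAML) model description: segments, joints,
#' muscles, contact spheres, knee ligament, AFO, Hill-curve and energetics
#' constants, and the reflex-controller wiring with its optimization bounds.
#'
#' @param path path to a model YAML file; defaults to the packaged planar
#'   7-segment / 9-DOF, 18-muscle model.
#' @return an object of class `"afo_model"` (a nested list mirroring the
#'   file).
#' @export
read_model_config <- function(path = default_model_path()) {
  m <- yaml::read_yaml(path)
  m$source <- path
  class(m) <- "afo_model"
  validate_model(m)
  m
}

#' @rdname read_model_config
#' @export
default_model_path <- function()
  system.file("extdata", "planar_gait_model.yaml", package = "afosim",
              mustWork = TRUE)

#' @rdname read_model_config
#' @export
default_model <- function() read_model_config()

#' Write a model configuration back to structured text
#' @param model an `afo_model`.
#' @param path output file path.
#' @export
write_model_config <- function(model, path) {
  m <- unclass(model)
  m$source <- NULL
  yaml::write_yaml(m, path)
  invisible(path)
}

#' @export
print.afo_model <- function(x, ...) {
  cat(sprintf("Planar walking model '%s': %d segments, %d DOF, %d muscles/leg\n",
              x$name, length(x$segments), 9L, length(x$muscles)))
  cat(sprintf("  body mass %.2f kg, gravity %.2f m/s^2\n",
              x$body_mass, x$gravity))
  if (!is.null(x$variant))
    cat(sprintf("  variant: weakness %.2f, passive x%.2f, mass x%.2f, speed %s\n",
                x$variant$weakness, x$variant$passive_scale,
                x$variant$mass_factor,
                if (is.null(x$variant$speed)) "free" else
                  paste0(x$variant$speed, " m/s")))
  invisible(x)
}

validate_model <- function(m) {
  stopifnot(length(m$segments) == 7L, length(m$muscles) == 9L)
  masses <- vapply(m$segments, function(s) s$mass, 0)
  if (any(masses <= 0)) stop("all segment masses must be positive")
  if (abs(sum(masses) - m$body_mass) > 1e-9)
    stop("segment masses must sum to body_mass (",
         sum(masses), " vs ", m$body_mass, ")")
  for (mu in m$muscles)
    if (mu$fmax <= 0 || mu$lopt <= 0 || mu$lslack <= 0)
      stop("muscle F_max and lengths must be positive")
  invisible(m)
}

coord_names <- function()
  c("pelvis_x", "pelvis_y", "pelvis_tilt", "hip_r", "knee_r", "ankle_r",
    "hip_l", "knee_l", "ankle_l")

phase_names <- function()
  c("early_stance", "late_stance", "liftoff", "swing", "landing")

# ---------------------------------------------------------------------------
# Controller parameter vector
# ---------------------------------------------------------------------------

#' Controller parameter table
#'
#' The flattened CMA-ES search space: every reflex gain (and length offset),
#' the trunk-PD parameters, phase-transition thresholds, and the initial
#' pose.  The vector layout is fixed by the configuration order, so a
#' parameter vector round-trips losslessly between its flat and named forms.
#'
#' @param model an `afo_model`.
#' @return data frame with columns `name`, `init`, `lower`, `upper`.
#' @export
controller_params <- function(model) {
  ctl <- model$controller
  nm <- character(); init <- lower <- upper <- numeric()
  add <- function(name, triple) {
    nm <<- c(nm, name)
    init <<- c(init, triple[[1]]); lower <<- c(lower, triple[[2]])
    upper <<- c(upper, triple[[3]])
  }
  for (i in seq_along(ctl$reflexes)) {
    e <- ctl$reflexes[[i]]
    base <- sprintf("r%02d_%s_%s", i, e$target,
                    switch(e$type, C = "const",
                           F = paste0("F_", e$source),
                           L = paste0("L_", e$source)))
    add(paste0(base, "_gain"), e$gain)
    if (e$type == "L") add(paste0(base, "_l0"), e$l0)
  }
  for (tgt in ctl$trunk_pd$targets)
    add(paste0("pd_", tgt$muscle, "_gain"), tgt$gain)
  add("pd_theta0", ctl$trunk_pd$theta0)
  add("pd_kd_ratio", ctl$trunk_pd$kd_ratio)
  for (tn in c("load_on", "load_off", "d_ls", "d_la"))
    add(paste0("thr_", tn), ctl$thresholds[[tn]])
  for (pn in c("pitch", "hip_r", "knee_r", "ankle_r", "hip_l", "knee_l",
               "ankle_l", "vx"))
    add(paste0("init_", pn), ctl$initial_pose[[pn]])
  data.frame(name = nm, init = init, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

#' Convert between flat and named controller parameter forms
#'
#' @param model an `afo_model`.
#' @param x named list (or named vector) of parameter values.
#' @return `controller_vector` returns the named numeric vector of initial
#'   values (or of `x` reordered); `controller_list` the named list form.
#' @export
controller_vector <- function(model, x = NULL) {
  tab <- controller_params(model)
  v <- tab$init
  names(v) <- tab$name
  if (!is.null(x)) {
    x <- unlist(x)
    bad <- setdiff(names(x), tab$name)
    if (length(bad)) stop("unknown controller parameters: ",
                          paste(bad, collapse = ", "))
    v[names(x)] <- x
  }
  v
}

#' @rdname controller_vector
#' @param v named numeric vector.
#' @export
controller_list <- function(model, v) {
  tab <- controller_params(model)
  stopifnot(length(v) == nrow(tab))
  as.list(stats::setNames(as.numeric(v), tab$name))
}

#' Serialize controller parameters as flat key = value text
#'
#' @param v named parameter vector.
#' @param path output path.
#' @export
write_controller_params <- function(v, path) {
  writeLines(sprintf("%s = %.17g", names(v), as.numeric(v)), path)
  invisible(path)
}

#' @rdname write_controller_params
#' @export
read_controller_params <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) as.numeric(trimws(x[2])), 0),
                  vapply(kv, function(x) trimws(x[1]), ""))
}

# ---------------------------------------------------------------------------
# Compilation to flat engine arrays
# ---------------------------------------------------------------------------

# Compile the nested model description into the flat numeric arrays the C++
# engine consumes.  Segment order: trunk, thigh_r, shank_r, foot_r, thigh_l,
# shank_l, foot_l; 0-based indices on the C++ side.
compile_model <- function(model) {
  segs <- model$segments
  seg_names <- names(segs)
  cn <- coord_names()
  ns <- length(segs)
  parent <- integer(ns); anchor <- matrix(0, ns, 2); com <- matrix(0, ns, 2)
  mass <- numeric(ns); inertia <- numeric(ns)
  G <- matrix(0, ns, 9)
  for (i in seq_len(ns)) {
    s <- segs[[i]]
    mass[i] <- s$mass; inertia[i] <- s$inertia
    com[i, ] <- unlist(s$com)
    if (is.null(s$parent)) {
      parent[i] <- -1L
      G[i, match("pelvis_tilt", cn)] <- 1
    } else {
      p <- match(s$parent, seg_names)
      parent[i] <- p - 1L
      anchor[i, ] <- unlist(s$anchor)
      G[i, ] <- G[p, ]
      G[i, match(s$coord, cn)] <- s$sign
    }
  }

  mus <- model$muscles
  mnames <- names(mus)
  nm1 <- length(mus)
  fmax <- lopt <- lslack <- hgt <- vmax <- tact <- tdeact <- fpas <-
    ften <- delay <- numeric(2 * nm1)
  path_seg <- integer(0); path_xy <- NULL; path_ptr <- 0L
  seg_for <- function(base, leg)
    match(if (base == "trunk") "trunk" else paste0(base, "_", leg),
          seg_names) - 1L
  for (leg in c("r", "l")) {
    off <- if (leg == "r") 0L else nm1
    for (j in seq_len(nm1)) {
      mu <- mus[[j]]; i <- off + j
      fmax[i] <- mu$fmax; lopt[i] <- mu$lopt; lslack[i] <- mu$lslack
      hgt[i] <- mu$lopt * sin(mu$penn); vmax[i] <- mu$vmax
      tact[i] <- mu$tau_act; tdeact[i] <- mu$tau_deact
      fpas[i] <- if (is.null(mu$fpas_scale)) 1 else mu$fpas_scale
      ften[i] <- if (is.null(mu$ften_scale)) 1 else mu$ften_scale
      delay[i] <- mu$delay
      for (pt in mu$path) {
        path_seg <- c(path_seg, seg_for(pt[[1]], leg))
        path_xy <- rbind(path_xy, c(pt[[2]], pt[[3]]))
      }
      path_ptr <- c(path_ptr, length(path_seg))
    }
  }

  sph <- model$contact$spheres
  nsp1 <- length(sph)
  sph_seg <- integer(0); sph_xy <- NULL; sph_r <- numeric(0)
  for (leg in c("r", "l")) for (s in sph) {
    sph_seg <- c(sph_seg, seg_for(s$segment, leg))
    sph_xy <- rbind(sph_xy, unlist(s$pos))
    sph_r <- c(sph_r, s$radius)
  }

  # controller wiring -> index arrays into the parameter vector
  tab <- controller_params(model)
  pidx <- function(n) match(n, tab$name) - 1L
  ctl <- model$controller
  ph <- phase_names()
  mask_of <- function(phs) sum(2L^(match(phs, ph) - 1L))
  r_target <- r_type <- r_source <- r_mask <- r_gain <- r_l0 <- integer(0)
  for (i in seq_along(ctl$reflexes)) {
    e <- ctl$reflexes[[i]]
    base <- sprintf("r%02d_%s_%s", i, e$target,
                    switch(e$type, C = "const",
                           F = paste0("F_", e$source),
                           L = paste0("L_", e$source)))
    r_target <- c(r_target, match(e$target, mnames) - 1L)
    r_type <- c(r_type, match(e$type, c("C", "F", "L")) - 1L)
    r_source <- c(r_source,
                  if (is.null(e$source)) 0L else match(e$source, mnames) - 1L)
    r_mask <- c(r_mask, mask_of(e$phases))
    r_gain <- c(r_gain, pidx(paste0(base, "_gain")))
    r_l0 <- c(r_l0, if (e$type == "L") pidx(paste0(base, "_l0")) else -1L)
  }
  pd <- ctl$trunk_pd
  pd_muscle <- vapply(pd$targets, function(t) match(t$muscle, mnames) - 1L, 0L)
  pd_gain <- vapply(pd$targets,
                    function(t) pidx(paste0("pd_", t$muscle, "_gain")), 0L)
  pd_sign <- vapply(pd$targets, function(t) as.integer(t$sign), 0L)

  list(parent = parent, G = G, anchor = anchor, com = com, mass = mass,
       inertia = inertia, gravity = model$gravity,
       body_mass = model$body_mass,
       m_fmax = fmax, m_lopt = lopt, m_lslack = lslack, m_h = hgt,
       m_vmax = vmax, m_tact = tact, m_tdeact = tdeact, m_fpas = fpas,
       m_ften = ften, m_delay = delay,
       path_seg = path_seg, path_ptr = as.integer(path_ptr),
       path_xy = path_xy,
       curves = unlist(model$curves[c("fl_width", "kpe", "e0", "eps_iso",
                                      "kten", "fvmax", "af", "damping")]),
       sph_seg = sph_seg, sph_xy = sph_xy, sph_r = sph_r,
       contact = unlist(model$contact[c("stiffness", "exponent",
                                        "dissipation", "friction",
                                        "v_reg")]),
       ligament = unlist(model$knee_ligament[c("k", "c", "flex_limit",
                                               "ext_limit")]),
       knee_q = match(c("knee_r", "knee_l"), cn) - 1L,
       ankle_q = match(c("ankle_r", "ankle_l"), cn) - 1L,
       hip_q = match(c("hip_r", "hip_l"), cn) - 1L,
       foot_seg = match(c("foot_r", "foot_l"), seg_names) - 1L,
       metab = unlist(model$metabolics[c("basal", "act_coef", "maint_coef",
                                         "short_coef", "specific_tension",
                                         "density")]),
       r_target = r_target, r_type = r_type, r_source = r_source,
       r_mask = r_mask, r_gain = r_gain, r_l0 = r_l0,
       pd_muscle = as.integer(pd_muscle), pd_gain = as.integer(pd_gain),
       pd_sign = pd_sign, pd_theta0 = pidx("pd_theta0"),
       pd_kdr = pidx("pd_kd_ratio"), pd_mask = mask_of(pd$phases),
       th_idx = vapply(c("thr_load_on", "thr_load_off", "thr_d_ls",
                         "thr_d_la"), pidx, 0L),
       pose_idx = vapply(paste0("init_", c("pitch", "hip_r", "knee_r",
                                           "ankle_r", "hip_l", "knee_l",
                                           "ankle_l")), pidx, 0L),
       vx_idx = pidx("init_vx"), npar = nrow(tab),
       pf_local = match(c("soleus", "gastrocnemius"), mnames) - 1L,
       head_seg = match("trunk", seg_names) - 1L,
       head_xy = c(0, segs$trunk$length),
       muscle_names = c(paste0(mnames, "_r"), paste0(mnames, "_l")))
}

# ---------------------------------------------------------------------------
# R-native kinematics (independent of the C++ pass; used for energy audits
# and as a cross-check of the engine's kinematics)
# ---------------------------------------------------------------------------

rot2 <- function(th, v) c(cos(th) * v[1] - sin(th) * v[2],
                          sin(th) * v[1] + cos(th) * v[2])
drot2 <- function(th, v) c(-sin(th) * v[1] - cos(th) * v[2],
                           cos(th) * v[1] - sin(th) * v[2])

#' Segment kinematics at a model state
#'
#' Forward pass over the segment tree: absolute segment angles, origins and
#' centre-of-mass positions and velocities for generalized state `(q, qd)`.
#' Implemented in R independently of the simulation engine.
#'
#' @param model an `afo_model`.
#' @param q,qd generalized positions (rad, m) and velocities.
#' @return list with `theta`, `thetad`, `origin`, `com`, `com_vel`
#'   (matrices with one row per segment, ordered as in the configuration).
#' @export
segment_kinematics <- function(model, q, qd = rep(0, 9)) {
  cm <- compile_model(model)
  ns <- length(cm$mass)
  theta <- as.numeric(cm$G %*% q)
  thetad <- as.numeric(cm$G %*% qd)
  O <- vO <- matrix(0, ns, 2)
  for (s in seq_len(ns)) {
    p <- cm$parent[s] + 1L
    if (p == 0L) {
      O[s, ] <- q[1:2]; vO[s, ] <- qd[1:2]
    } else {
      O[s, ] <- O[p, ] + rot2(theta[p], cm$anchor[s, ])
      vO[s, ] <- vO[p, ] + thetad[p] * drot2(theta[p], cm$anchor[s, ])
    }
  }
  comw <- comv <- matrix(0, ns, 2)
  for (s in seq_len(ns)) {
    comw[s, ] <- O[s, ] + rot2(theta[s], cm$com[s, ])
    comv[s, ] <- vO[s, ] + thetad[s] * drot2(theta[s], cm$com[s, ])
  }
  rownames(O) <- rownames(comw) <- names(model$segments)
  list(theta = theta, thetad = thetad, origin = O, com = comw,
       com_vel = comv)
}

#' Total mechanical energy of a model state
#'
#' Kinetic plus gravitational potential energy, used in the passive energy
#' audits.
#'
#' @inheritParams segment_kinematics
#' @return energy in J.
#' @export
mechanical_energy <- function(model, q, qd) {
  cm <- compile_model(model)
  k <- segment_kinematics(model, q, qd)
  ke <- sum(0.5 * cm$mass * rowSums(k$com_vel^2)) +
    sum(0.5 * cm$inertia * k$thetad^2)
  pe <- sum(cm$mass * model$gravity * k$com[, 2])
  ke + pe
}

# ---------------------------------------------------------------------------
# Weakness / variant transformations
# ---------------------------------------------------------------------------

#' Impose plantarflexor weakness and altered passive stiffness
#'
#' Reduces the maximal isometric force of soleus and gastrocnemius by the
#' fraction `strength_reduction`, while rescaling their normalized passive
#' fiber and tendon force-length curves by `1/(1 - strength_reduction)` so
#' the absolute passive curves match the unimpaired model exactly.  The
#' absolute passive fiber force is then multiplied by `passive_scale`
#' (independent variation of passive plantarflexor stiffness).
#'
#' @param model an `afo_model`.
#' @param strength_reduction fraction of F_max removed, in `[0, 1)`.
#' @param passive_scale multiplier on the absolute passive plantarflexor
#'   force (1 = normal).
#' @return the transformed model.
#' @export
apply_weakness <- function(model, strength_reduction = 0, passive_scale = 1) {
  s <- strength_reduction
  if (s < 0 || s >= 1)
    stop("strength_reduction must be in [0, 1); s = 1 is degenerate")
  if (passive_scale <= 0) stop("passive_scale must be positive")
  if (s == 0 && passive_scale == 1) return(model)   # exact identity
  for (mn in c("soleus", "gastrocnemius")) {
    mu <- model$muscles[[mn]]
    f0 <- if (is.null(mu$fpas_scale)) 1 else mu$fpas_scale
    t0 <- if (is.null(mu$ften_scale)) 1 else mu$ften_scale
    mu$fmax <- mu$fmax * (1 - s)
    mu$fpas_scale <- f0 * passive_scale / (1 - s)
    mu$ften_scale <- t0 / (1 - s)
    model$muscles[[mn]] <- mu
  }
  model
}

#' Define a model variant of the in-silico experiment
#'
#' The study grid varies bilateral plantarflexor weakness (40, 60, 80, 90%
#' strength reduction), passive plantarflexor stiffness (20-200% of normal),
#' segment mass (+10%, +30%, without changing muscle forces) and walking
#' speed (free, or enforced 0.75 / 1.0 / 1.2 m/s).  The baseline model is
#' 80% weakness with all other factors at their reference level.
#'
#' @param weakness strength reduction fraction in `[0, 1)`.
#' @param passive_scale passive plantarflexor stiffness multiplier (> 0).
#' @param mass_factor segment-mass multiplier (> 0).
#' @param speed `NULL` for self-selected speed, or an enforced speed (m/s).
#' @return list of class `"model_variant"`.
#' @export
model_variant <- function(weakness = 0.8, passive_scale = 1,
                          mass_factor = 1, speed = NULL) {
  if (!is.numeric(weakness) || weakness < 0 || weakness >= 1)
    stop("unknown weakness level: must be a fraction in [0, 1)")
  if (!is.numeric(passive_scale) || passive_scale <= 0)
    stop("unknown passive_scale level: must be > 0")
  if (!is.numeric(mass_factor) || mass_factor <= 0)
    stop("unknown mass_factor level: must be > 0")
  if (!is.null(speed) && (!is.numeric(speed) || speed <= 0))
    stop("unknown speed level: must be NULL (free) or > 0")
  structure(list(weakness = weakness, passive_scale = passive_scale,
                 mass_factor = mass_factor, speed = speed),
            class = "model_variant")
}

#' Build a model variant
#'
#' Applies, in order: plantarflexor weakness, passive-stiffness scaling,
#' segment-mass scaling (muscle forces untouched), and records the enforced
#' speed (if any).  The identity variant returns a model identical to the
#' base (bit-exact, apart from the recorded variant tag).
#'
#' @param model base `afo_model`.
#' @param variant a [model_variant()].
#' @return transformed `afo_model` with the variant recorded in
#'   `model$variant`.
#' @export
build_variant <- function(model, variant = model_variant()) {
  stopifnot(inherits(variant, "model_variant"))
  out <- model
  identity_variant <- variant$weakness == 0 && variant$passive_scale == 1 &&
    variant$mass_factor == 1 && is.null(variant$speed)
  if (identity_variant) return(model)
  if (variant$weakness > 0 || variant$passive_scale != 1)
    out <- apply_weakness(out, variant$weakness, variant$passive_scale)
  if (variant$mass_factor != 1) {
    for (sn in names(out$segments)) {
      out$segments[[sn]]$mass <- out$segments[[sn]]$mass * variant$mass_factor
      out$segments[[sn]]$inertia <-
        out$segments[[sn]]$inertia * variant$mass_factor
    }
    out$body_mass <- out$body_mass * variant$mass_factor
  }
  out$variant <- variant
  out
}
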