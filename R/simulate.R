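#' Run a forward walking simulation
#'
#' Integrates the full neuromusculoskeletal model (skeleton, muscles,
#' contact, reflex controller, energetics) for one bout.  Fixed-step
#' semi-implicit integration at `dt`; cost components and metabolic energy
#' are accumulated over the steady-state window after the transient.
#'
#' @param model an `afo_model`.
#' @param params controller parameter vector; defaults to the
#'   configuration's initial values ([controller_vector()]).
#' @param K_afo AFO torsional stiffness (Nm/degree, >= 0; 0 = no AFO).
#' @param duration bout duration (s, default 10).
#' @param dt integration step (s, default 1e-4).
#' @param record_dt trajectory sampling interval (s).
#' @param transient transient discarded before computing energy and gait
#'   summaries (s, default 2).
#' @param act_threshold plantarflexor activation threshold for the
#'   high-activation penalty (default 0.5).
#' @return object of class `"sim_result"`: list with `summary` (named
#'   vector: `t_end`, `fell`, `distance`, `mean_speed`, `cot`, `E_metab`,
#'   `head_acc`, `joint_viol`, `act_excess`, `afo_work`), `traj` (list of
#'   recorded matrices: `time`, `q`, `qd`, `act`, `Fmt`, `lm`, `u`, `grf`,
#'   `phase`), `options`, `K_afo`, `body_mass`, `muscle_names`.
#' @export
simulate_walk <- function(model, params = NULL, K_afo = 0, duration = 10,
                          dt = 1e-4, record_dt = 0.005, transient = 2,
                          act_threshold = 0.5) {
  if (K_afo < 0) stop("AFO stiffness must be >= 0")
  if (is.null(params)) params <- controller_vector(model)
  cm <- compile_model(model)
  opt <- engine_options(duration = duration, dt = dt, record_dt = record_dt,
                        K_afo = K_afo, transient = transient,
                        act_threshold = act_threshold)
  out <- cpp_simulate(cm, as.numeric(params), opt)
  structure(list(summary = out$summary, traj = out$traj, options = opt,
                 K_afo = K_afo, body_mass = model$body_mass,
                 muscle_names = cm$muscle_names, params = params),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Walking simulation (K_afo = %.2f Nm/degree): %s\n", x$K_afo,
              if (s[["fell"]] > 0) sprintf("FELL at t = %.2f s", s[["t_end"]])
              else sprintf("completed %.1f s", s[["t_end"]])))
  if (is.finite(s[["mean_speed"]]))
    cat(sprintf("  speed %.2f m/s, COT %.2f J/kg/m over the steady window\n",
                s[["mean_speed"]], s[["cot"]]))
  invisible(x)
}

#' @export
plot.sim_result <- function(x, ...) {
  tr <- x$traj
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  deg <- 180 / pi
  plot(tr$time, tr$q[, 5] * deg, type = "l", xlab = "time (s)",
       ylab = "angle (deg)", col = "firebrick", ...)
  graphics::lines(tr$time, tr$q[, 6] * deg, col = "steelblue")
  graphics::legend("topright", c("knee R", "ankle R"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  plot(tr$time, tr$grf[, 2], type = "l", xlab = "time (s)",
       ylab = "vertical GRF (N)", col = "firebrick", ...)
  graphics::lines(tr$time, tr$grf[, 5], col = "steelblue")
  invisible(x)
}

# joint world positions for every recorded frame (rows = frames)
joint_positions <- function(model, qmat) {
  n <- nrow(qmat)
  ankle_r <- knee_r <- hip <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    k <- segment_kinematics(model, qmat[i, ])
    hip[i, ] <- k$origin["trunk", ]
    knee_r[i, ] <- k$origin["shank_r", ]
    ankle_r[i, ] <- k$origin["foot_r", ]
  }
  list(hip = hip, knee_r = knee_r, ankle_r = ankle_r)
}

#' Gait summary of a walking simulation
#'
#' Segments steady-state gait cycles from the right vertical GRF, computes
#' the stance-phase summary parameters used in the stiffness analyses
#' (maximal ankle dorsiflexion, peak ankle moment, minimal knee angle,
#' minimal external knee moment; moments mass-normalized from the ground
#' reaction force and centre of pressure), and returns time-normalized
#' 101-point curves per gait variable.
#'
#' @param sim a [simulate_walk()] result.
#' @param model the `afo_model` that produced it.
#' @param grf_threshold contact threshold for cycle events (N, default 20).
#' @return list with `n_cycles`, `per_cycle` (data frame), mean summary
#'   scalars (`ankle_angle_max` (deg), `ankle_moment_max` (Nm/kg),
#'   `knee_angle_min` (deg), `knee_moment_min` (Nm/kg)), `mean_speed`,
#'   `cot`, and `curves` (named list of 101-point cycle-averaged curves).
#'   Returns `n_cycles = 0` with `NA` summaries when no complete steady
#'   cycle exists.
#' @export
gait_summary <- function(sim, model, grf_threshold = 20) {
  tr <- sim$traj
  s <- sim$summary
  empty <- list(n_cycles = 0L, per_cycle = NULL, ankle_angle_max = NA_real_,
                ankle_moment_max = NA_real_, knee_angle_min = NA_real_,
                knee_moment_min = NA_real_,
                mean_speed = s[["mean_speed"]], cot = s[["cot"]],
                curves = NULL)
  w <- tr$time >= sim$options$transient
  if (sum(w) < 10 || s[["fell"]] > 0) return(empty)
  tt <- tr$time[w]
  grf_y <- tr$grf[w, 2]
  ev <- tryCatch(segment_cycles(grf_y, tt, grf_threshold),
                 error = function(e) NULL)
  if (is.null(ev)) return(empty)
  deg <- 180 / pi
  qw <- tr$q[w, , drop = FALSE]
  qdw <- tr$qd[w, , drop = FALSE]
  jp <- joint_positions(model, qw)
  mass <- sim$body_mass
  copx <- tr$grf[w, 3]; fx <- tr$grf[w, 1]; fy <- grf_y
  mz_about <- function(joint) {
    rx <- copx - joint[, 1]; ry <- -joint[, 2]
    (rx * fy - ry * fx) / mass
  }
  loaded <- fy > grf_threshold
  ankle_mom <- ifelse(loaded, mz_about(jp$ankle_r), 0)
  knee_mom <- ifelse(loaded, mz_about(jp$knee_r), 0)
  hip_mom <- ifelse(loaded, mz_about(jp$hip), 0)
  ankle_ang <- qw[, 6] * deg; knee_ang <- qw[, 5] * deg
  hip_ang <- qw[, 4] * deg
  ankle_pow <- ankle_mom * (-qdw[, 6])
  knee_pow <- -knee_mom * qdw[, 5]
  hip_pow <- hip_mom * qdw[, 4]

  vars <- list(ankle_angle = ankle_ang, knee_angle = knee_ang,
               hip_angle = hip_ang, ankle_moment = ankle_mom,
               knee_moment = knee_mom, hip_moment = hip_mom,
               ankle_power = ankle_pow, knee_power = knee_pow,
               hip_power = hip_pow)

  cyc <- ev$cycles
  per <- NULL
  curves_acc <- lapply(vars, function(v) matrix(0, 0, 101))
  for (ci in seq_len(nrow(cyc))) {
    sel <- tt >= cyc$start[ci] & tt <= cyc$end[ci]
    if (sum(sel) < 8) next
    tc <- tt[sel]
    st <- loaded[sel]
    # stance: from heel strike until the foot first unloads
    off <- which(!st)
    stance <- if (length(off)) seq_len(max(1L, off[1] - 1L)) else
      seq_along(tc)
    row <- data.frame(
      cycle = ci,
      duration = cyc$end[ci] - cyc$start[ci],
      ankle_angle_max = max(ankle_ang[sel][stance]),
      ankle_moment_max = max(ankle_mom[sel][stance]),
      knee_angle_min = min(knee_ang[sel][stance]),
      knee_moment_min = min(knee_mom[sel][stance]))
    per <- rbind(per, row)
    for (vn in names(vars))
      curves_acc[[vn]] <- rbind(curves_acc[[vn]],
                                time_normalize(vars[[vn]][sel], tc))
  }
  if (is.null(per) || nrow(per) == 0) return(empty)
  curves <- lapply(curves_acc, colMeans)
  list(n_cycles = nrow(per), per_cycle = per,
       ankle_angle_max = mean(per$ankle_angle_max),
       ankle_moment_max = mean(per$ankle_moment_max),
       knee_angle_min = mean(per$knee_angle_min),
       knee_moment_min = mean(per$knee_moment_min),
       mean_speed = s[["mean_speed"]], cot = s[["cot"]], curves = curves)
}

#' Export a simulated trajectory as OpenSim storage text
#'
#' Tab-separated `.sto` dialect: a short header, then column labels with
#' time first.
#'
#' @param sim a [simulate_walk()] result.
#' @param path output path.
#' @export
write_sto <- function(sim, path) {
  tr <- sim$traj
  deg <- 180 / pi
  d <- data.frame(time = tr$time)
  cn <- coord_names()
  for (j in 1:9)
    d[[cn[j]]] <- if (j <= 2) tr$q[, j] else tr$q[, j] * deg
  d$grf_r_x <- tr$grf[, 1]; d$grf_r_y <- tr$grf[, 2]
  d$grf_l_x <- tr$grf[, 4]; d$grf_l_y <- tr$grf[, 5]
  for (j in seq_along(sim$muscle_names))
    d[[paste0("act_", sim$muscle_names[j])]] <- tr$act[, j]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("afosim trajectory", "version=1",
               sprintf("nRows=%d", nrow(d)),
               sprintf("nColumns=%d", ncol(d)),
               "inDegrees=yes", "endheader"), con)
  utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sto
#' @export
read_sto <- function(path) {
  ln <- readLines(path)
  h <- which(ln == "endheader")[1]
  utils::read.delim(path, skip = h)
}
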