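# Synthetic reference data: normative-style gait bands, noisy cycle cohorts,
# and energy-stiffness sweep tables with known ground truth.  These stand in
# for non-public trial data; they emulate the shape and variability structure
# of normative sagittal gait curves, not any particular cohort.

# Control points (% gait cycle, value) for smooth periodic normative-style
# sagittal curves.  Angles in degrees, moments in Nm/kg (internal, extensor/
# plantarflexor positive), powers in W/kg.  Values chosen to resemble
# textbook normative walking at ~1.2 m/s.
.band_shapes <- list(
  ankle_angle  = cbind(c(0, 8, 20, 35, 48, 57, 65, 80, 92, 100),
                       c(0, -5, 3, 8, 11, 2, -16, -4, 1, 0)),
  knee_angle   = cbind(c(0, 8, 15, 25, 40, 50, 62, 72, 85, 95, 100),
                       c(5, 15, 18, 10, 5, 6, 32, 60, 25, 6, 5)),
  hip_angle    = cbind(c(0, 10, 30, 50, 62, 75, 88, 100),
                       c(28, 24, 8, -8, -5, 18, 28, 28)),
  ankle_moment = cbind(c(0, 5, 12, 30, 48, 56, 62, 75, 100),
                       c(0, -0.15, 0.2, 0.8, 1.45, 1.1, 0.1, 0, 0)),
  knee_moment  = cbind(c(0, 6, 14, 25, 40, 52, 62, 75, 90, 100),
                       c(0, 0.35, 0.45, 0.1, -0.25, -0.2, 0.1, 0.05, 0, 0)),
  hip_moment   = cbind(c(0, 8, 20, 35, 50, 60, 72, 88, 100),
                       c(0.3, 0.8, 0.4, -0.2, -0.8, -0.5, 0.1, 0.2, 0.3)),
  ankle_power  = cbind(c(0, 6, 15, 30, 42, 50, 56, 61, 68, 80, 100),
                       c(0, -0.4, -0.3, -0.5, -0.9, 0.5, 3.3, 1.5, 0, 0, 0)),
  knee_power   = cbind(c(0, 6, 14, 22, 35, 50, 60, 70, 82, 93, 100),
                       c(0, -0.8, 0.6, 0.2, 0, -0.4, -1.2, -0.6, 0.2, -0.9, 0)),
  hip_power    = cbind(c(0, 8, 18, 33, 45, 55, 62, 72, 85, 100),
                       c(0.2, 0.9, 0.5, -0.2, -0.6, 0.7, 1.3, 0.6, 0.1, 0.2))
)

# relative SD amplitude per variable family (fraction of curve range)
.band_sd_frac <- c(angle = 0.12, moment = 0.15, power = 0.22)

.band_family <- function(variable)
  c("angle", "moment", "power")[pmatch(sub("^.*_", "", variable),
                                       c("angle", "moment", "power"))]

periodic_curve <- function(ctrl, n_points = 101L) {
  x <- ctrl[, 1]; y <- ctrl[, 2]
  if (x[1] != 0) { x <- c(0, x); y <- c(y[length(y)], y) }
  if (x[length(x)] != 100) { x <- c(x, 100); y <- c(y, y[1]) }
  y[length(y)] <- y[1]                      # enforce periodicity
  stats::spline(x, y, method = "periodic",
                xout = seq(0, 100, length.out = n_points))$y
}

#' Configuration for synthetic reference gait bands
#'
#' @param variables which gait variables to generate; any subset of the nine
#'   sagittal ankle/knee/hip angle, moment and power curves.
#' @param n_subjects nominal number of subjects the band summarises
#'   (default 11).
#' @param sd_amplitude multiplier on the built-in SD profiles; must be > 0
#'   (a reference band requires strictly positive SD everywhere).
#' @param n_points points per gait cycle (default 101).
#' @return list of class `"band_config"`.
#' @export
band_config <- function(variables = names(.band_shapes), n_subjects = 11L,
                        sd_amplitude = 1, n_points = 101L) {
  stopifnot(all(variables %in% names(.band_shapes)))
  if (sd_amplitude <= 0)
    stop("sd_amplitude must be positive: a reference band needs SD > 0")
  if (n_subjects < 2L) stop("a reference band needs n_subjects >= 2")
  structure(list(variables = variables, n_subjects = n_subjects,
                 sd_amplitude = sd_amplitude, n_points = n_points),
            class = "band_config")
}

#' Generate synthetic normative-style reference gait bands
#'
#' Produces smooth 101-point mean and SD curves per gait variable from
#' built-in periodic spline shapes that emulate normative sagittal walking
#' data.  Deterministic given the configuration; the `seed` argument is
#' accepted for interface symmetry with the other generators and recorded in
#' the output.
#'
#' @param config a [band_config()].
#' @param seed integer seed, recorded in each band.
#' @return named list of reference bands; each band is a list with `mean`,
#'   `sd` (both length `n_points`, SD > 0 everywhere), `n`, `variable`.
#' @examples
#' bands <- gen_reference_band(band_config())
#' range(bands$ankle_angle$mean)
#' @export
gen_reference_band <- function(config = band_config(), seed = 1L) {
  stopifnot(inherits(config, "band_config"))
  out <- lapply(config$variables, function(v) {
    m <- periodic_curve(.band_shapes[[v]], config$n_points)
    fam <- .band_family(v)
    rng <- diff(range(m))
    # smooth, strictly positive SD profile: widest near push-off/swing
    pct <- seq(0, 1, length.out = config$n_points)
    shape <- 1 + 0.45 * sin(2 * pi * pct - 0.6) + 0.25 * sin(4 * pi * pct)
    sd <- config$sd_amplitude * .band_sd_frac[[fam]] * rng *
      (0.55 + 0.45 * (shape - min(shape)) / diff(range(shape)))
    list(mean = m, sd = sd, n = config$n_subjects, variable = v, seed = seed)
  })
  names(out) <- config$variables
  out
}

#' Generate a cohort of noisy gait cycles around a reference band
#'
#' Each synthetic cycle is the band mean plus a smooth (low-frequency
#' correlated) periodic Gaussian perturbation scaled pointwise by the band
#' SD.  Smooth rather than white noise emulates between-subject gait
#' variability and gives the spatially correlated fields that 1D SPM cluster
#' inference assumes.
#'
#' @param band one reference band (list with `mean` and `sd`).
#' @param n number of cycles/subjects (>= 2).
#' @param noise_sd marginal SD of the perturbation in band-SD units
#'   (default 1: the cohort reproduces the band's variability).
#' @param smoothness spectral scale: Fourier harmonics are damped as
#'   `exp(-(k/smoothness)^2)`; smaller is smoother (default 3).
#' @param seed integer seed.
#' @return numeric matrix `n x length(band$mean)`, one cycle per row.
#' @export
gen_cycle_cohort <- function(band, n, noise_sd = 1, smoothness = 3,
                             seed = 1L) {
  stopifnot(n >= 2L, length(band$mean) == length(band$sd))
  set.seed(seed)
  Q <- length(band$mean)
  pct <- seq(0, 1, length.out = Q)
  kmax <- 12L
  # marginal variance of a0 + sum_{k>=1} (a_k cos + b_k sin), with
  # Var(a_k) = Var(b_k) = lambda_k, is sum_k lambda_k at every node;
  # normalize the spectrum so the perturbation has unit marginal variance
  lambda <- exp(-((0:kmax) / smoothness)^2)
  lambda <- lambda / sum(lambda)
  E <- matrix(0, n, Q)
  for (i in seq_len(n)) {
    e <- stats::rnorm(1, 0, sqrt(lambda[1]))
    for (k in 1:kmax) {
      ab <- stats::rnorm(2, 0, sqrt(lambda[k + 1]))
      e <- e + ab[1] * cos(2 * pi * k * pct) + ab[2] * sin(2 * pi * k * pct)
    }
    E[i, ] <- e
  }
  sweep(E, 2, band$sd * noise_sd, `*`) +
    matrix(band$mean, n, Q, byrow = TRUE)
}

#' Configuration for synthetic energy-stiffness sweep tables
#'
#' The cost-of-transport response is a convex cubic with its minimum at the
#' true optimal stiffness `K_star`:
#' `cot(K) = cot_min + curvature*(K - K_star)^2 + asym*(K - K_star)^3`,
#' with `asym` small enough that the argmin over the grid stays at `K_star`.
#' Gait parameters follow monotone linear trends with analytically known
#' normative-threshold crossings.
#'
#' @param K_star true energy-optimal stiffness (Nm/degree), inside the grid.
#' @param cot_min cost of transport at the optimum (J/kg/m).
#' @param curvature quadratic coefficient of the response (J/kg/m per
#'   (Nm/degree)^2).
#' @param asym cubic asymmetry coefficient (left/right slopes need not
#'   match).
#' @param noise_sd SD of additive Gaussian noise on COT (J/kg/m).
#' @param grid stiffness grid (default [stiffness_grid()]).
#' @param crossings named numeric vector of true threshold-crossing
#'   stiffnesses for `ankle_angle`, `ankle_moment`, `knee_angle`,
#'   `knee_moment`.
#' @param speed0 walking speed at zero stiffness (m/s); speed rises mildly
#'   with stiffness.
#' @return list of class `"sweep_config"`.
#' @export
sweep_config <- function(K_star = 3.8, cot_min = 3.4, curvature = 0.06,
                         asym = 0.003, noise_sd = 0.05,
                         grid = stiffness_grid(),
                         crossings = c(ankle_angle = 2.7, ankle_moment = 2.2,
                                       knee_angle = 2.1, knee_moment = 1.9),
                         speed0 = 0.88) {
  stopifnot(K_star > min(grid), K_star < max(grid), curvature > 0)
  # keep the second stationary point of the cubic outside the grid so the
  # argmin over the domain is K_star itself
  if (asym != 0) {
    other <- K_star - 2 * curvature / (3 * asym)
    if (other >= min(grid) && other <= max(grid))
      stop("asym too large: cubic has a second stationary point in the grid")
  }
  structure(list(K_star = K_star, cot_min = cot_min, curvature = curvature,
                 asym = asym, noise_sd = noise_sd, grid = grid,
                 crossings = crossings, speed0 = speed0),
            class = "sweep_config")
}

#' Generate a synthetic AFO stiffness sweep table with known ground truth
#'
#' @param config a [sweep_config()].
#' @param seed integer seed for the COT noise.
#' @return data frame of class `"sweep_table"` with columns `stiffness`,
#'   `cot`, `speed`, `ankle_angle_max`, `ankle_moment_max`, `knee_angle_min`,
#'   `knee_moment_min`, `ok`; the generating configuration is attached as
#'   attribute `"ground_truth"`.
#' @examples
#' sw <- gen_sweep_table(sweep_config(noise_sd = 0), seed = 1)
#' fit_optimum(sw)$K_opt      # recovers K_star
#' @export
gen_sweep_table <- function(config = sweep_config(), seed = 1L) {
  stopifnot(inherits(config, "sweep_config"))
  set.seed(seed)
  K <- config$grid
  d <- K - config$K_star
  cot <- config$cot_min + config$curvature * d^2 + config$asym * d^3 +
    stats::rnorm(length(K), 0, config$noise_sd)
  thr <- normative_thresholds()
  cx <- config$crossings
  # pathological values at K = 0, chosen per parameter; linear trends cross
  # each normative threshold exactly at the configured stiffness
  lin <- function(par) {
    row <- thr[thr$parameter == par, ]
    Kc <- cx[[par]]
    slope <- switch(par, ankle_angle = 4.0, knee_angle = 3.8,
                    ankle_moment = 0.17, knee_moment = 0.34)
    if (row$direction == "decrease") row$threshold + slope * (Kc - K)
    else row$threshold - slope * (Kc - K)
  }
  out <- data.frame(
    stiffness = K,
    cot = cot,
    speed = config$speed0 + 0.012 * K,
    ankle_angle_max = lin("ankle_angle"),
    ankle_moment_max = lin("ankle_moment"),
    knee_angle_min = lin("knee_angle"),
    knee_moment_min = lin("knee_moment"),
    ok = TRUE
  )
  attr(out, "ground_truth") <- config
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Write / read a reference band as CSV
#'
#' Plain-text band format: columns `pct` (0-100% gait cycle), `mean`, `sd`;
#' the subject count is stored in a `# n=` header comment.
#'
#' @param band reference band (list with `mean`, `sd`, `n`).
#' @param path file path.
#' @name band_io
#' @export
write_band_csv <- function(band, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d variable=%s", band$n,
                     if (is.null(band$variable)) "unknown" else band$variable),
             con)
  utils::write.csv(data.frame(pct = seq(0, 100,
                                        length.out = length(band$mean)),
                              mean = band$mean, sd = band$sd),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname band_io
#' @export
read_band_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  n <- as.integer(sub(".*n=([0-9]+).*", "\\1", hdr))
  variable <- sub(".*variable=([^ ]+).*", "\\1", hdr)
  d <- utils::read.csv(path, comment.char = "#")
  list(mean = d$mean, sd = d$sd, n = n, variable = variable)
}
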