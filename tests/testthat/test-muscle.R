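# Hill-type muscle layer: normalized curves, activation dynamics, the
# static equilibrium solver and the weakness transformation.

test_that("curve identities: optimal length, isometric velocity, monotony", {
  expect_equal(hill_curves(1, "active_fl"), 1)
  expect_lt(hill_curves(1.45, "active_fl"), hill_curves(1, "active_fl"))
  expect_equal(hill_curves(0, "fv"), 1)
  expect_equal(hill_curves(-1, "fv"), 0)
  expect_equal(hill_curves(-2, "fv"), 0)        # clamped beyond v_max
  l <- seq(0.8, 1.8, by = 0.01)
  expect_true(all(diff(hill_curves(l, "passive_fl")) >= 0))
  expect_true(all(hill_curves(l[l <= 1], "passive_fl") == 0))
  eps <- seq(-0.01, 0.1, by = 0.001)
  expect_true(all(diff(hill_curves(eps, "tendon_fl")) >= 0))
  expect_equal(hill_curves(0.049, "tendon_fl"), 1, tolerance = 1e-12)
  v <- seq(-1, 2, by = 0.01)
  expect_true(all(diff(hill_curves(v, "fv")) >= 0))
  expect_lt(max(hill_curves(v, "fv")), 1.4)
})

test_that("passive curve matches an independent formula evaluation", {
  # direct evaluation of the exponential passive form with the packaged
  # constants (kpe = 4, e0 = 0.6)
  l <- c(1.1, 1.3, 1.5)
  ref <- (exp(4 * (l - 1) / 0.6) - 1) / (exp(4) - 1)
  expect_equal(hill_curves(l, "passive_fl"), ref, tolerance = 1e-12)
})

test_that("activation dynamics: fixed point, saturation, closed form", {
  expect_equal(activation_dynamics(0.4, 0.4, 0.01), 0.4)
  a <- 0
  for (i in 1:300) a <- activation_dynamics(1, a, 0.01)
  expect_equal(a, 1, tolerance = 1e-9)
  # one-step update equals the exponential solution for constant input
  u <- 0.8; a0 <- 0.2; dt <- 0.004
  expect_equal(activation_dynamics(u, a0, dt),
               u + (a0 - u) * exp(-dt / 0.01), tolerance = 1e-12)
  u <- 0.1; a0 <- 0.9
  expect_equal(activation_dynamics(u, a0, dt),
               u + (a0 - u) * exp(-dt / 0.04), tolerance = 1e-12)
  # clipping
  expect_lte(activation_dynamics(1.7, 0.5, 0.1), 1)
  expect_gte(activation_dynamics(-2, 0.5, 0.1), 0)
})

test_that("rigid-tendon equilibrium at optimal length gives Fmax cos(penn)", {
  p <- list(fmax = 1000, lopt = 0.1, lslack = 0.2, penn = 0.2)
  lmt <- 0.2 + 0.1 * cos(0.2)
  st <- solve_equilibrium(p, lmt, 1, rigid_tendon = TRUE)
  expect_equal(st$lm_norm, 1, tolerance = 1e-6)
  expect_equal(st$tendon_force, 1000 * cos(0.2), tolerance = 1e-3)
})

test_that("passive-only equilibrium matches an in-test bisection oracle", {
  p <- list(fmax = 2000, lopt = 0.08, lslack = 0.25, penn = 0)
  lmt <- 0.25 + 0.08 * 1.25        # stretched: passive force engages
  st <- solve_equilibrium(p, lmt, 0)
  expect_true(st$converged)
  expect_lt(st$residual, 1e-8)
  # independent bisection over fiber length written out in the test
  cc <- afosim:::curve_constants()
  bal <- function(ln) {
    fp <- afosim:::cpp_hill_curves(ln, "passive_fl", cc)
    eps <- (lmt - ln * 0.08) / 0.25 - 1
    ft <- afosim:::cpp_hill_curves(eps, "tendon_fl", cc)
    fp - ft
  }
  lo <- 0.5; hi <- 2
  for (i in 1:60) { mid <- (lo + hi) / 2
    if (bal(mid) < 0) lo <- mid else hi <- mid }
  expect_equal(st$lm_norm, (lo + hi) / 2, tolerance = 1e-7)
  # and force balance holds in absolute units
  expect_equal(st$tendon_force,
               2000 * afosim:::cpp_hill_curves(st$lm_norm, "passive_fl", cc),
               tolerance = 1e-4)
})

test_that("compliant-tendon solution approaches the rigid-tendon limit", {
  p <- list(fmax = 1500, lopt = 0.09, lslack = 0.22, penn = 0.1)
  lmt <- 0.22 + 0.09 * cos(0.1) * 1.05
  rigid <- solve_equilibrium(p, lmt, 0.7, rigid_tendon = TRUE)
  # stiffen the tendon by inflating its normalized force scale
  stiff <- p; stiff$ften_scale <- 1e6
  soft <- solve_equilibrium(stiff, lmt, 0.7)
  expect_equal(soft$lm_norm, rigid$lm_norm, tolerance = 1e-3)
})

test_that("weakness transform: identity, F_max scaling, passive matching", {
  m <- test_model()
  expect_identical(apply_weakness(m, 0, 1), m)
  w <- apply_weakness(m, 0.8)
  expect_equal(w$muscles$soleus$fmax, 0.2 * m$muscles$soleus$fmax)
  expect_equal(w$muscles$gastrocnemius$fmax,
               0.2 * m$muscles$gastrocnemius$fmax)
  for (mn in setdiff(names(m$muscles), c("soleus", "gastrocnemius")))
    expect_identical(w$muscles[[mn]], m$muscles[[mn]])
  # absolute passive fiber force preserved at every length (1e-9 relative)
  cc <- afosim:::curve_constants(m)
  l <- seq(1.05, 1.6, by = 0.05)
  for (mn in c("soleus", "gastrocnemius")) {
    f0 <- m$muscles[[mn]]$fmax *
      afosim:::cpp_hill_curves(l, "passive_fl", cc)
    f1 <- w$muscles[[mn]]$fmax * w$muscles[[mn]]$fpas_scale *
      afosim:::cpp_hill_curves(l, "passive_fl", cc)
    expect_lt(max(abs(f1 - f0) / f0), 1e-9)
    # absolute tendon curve preserved too
    eps <- seq(0.01, 0.08, by = 0.01)
    t0 <- m$muscles[[mn]]$fmax *
      afosim:::cpp_hill_curves(eps, "tendon_fl", cc)
    t1 <- w$muscles[[mn]]$fmax * w$muscles[[mn]]$ften_scale *
      afosim:::cpp_hill_curves(eps, "tendon_fl", cc)
    expect_lt(max(abs(t1 - t0) / t0), 1e-9)
  }
  # passive scale multiplies the absolute passive force
  w2 <- apply_weakness(m, 0.8, 0.2)
  f2 <- w2$muscles$soleus$fmax * w2$muscles$soleus$fpas_scale *
    afosim:::cpp_hill_curves(l, "passive_fl", cc)
  f0 <- m$muscles$soleus$fmax * afosim:::cpp_hill_curves(l, "passive_fl", cc)
  expect_equal(f2, 0.2 * f0, tolerance = 1e-9)
  expect_error(apply_weakness(m, 1), "degenerate")
})

test_that("weakness commutes with curve evaluation over a length grid", {
  m <- test_model()
  w <- apply_weakness(m, 0.6, 1.5)
  cc <- afosim:::curve_constants(m)
  l <- seq(0.7, 1.7, by = 0.02)
  # evaluating the transformed model's absolute passive curve equals
  # transforming the base model's absolute passive curve
  base_abs <- m$muscles$soleus$fmax *
    afosim:::cpp_hill_curves(l, "passive_fl", cc)
  trans_abs <- w$muscles$soleus$fmax * w$muscles$soleus$fpas_scale *
    afosim:::cpp_hill_curves(l, "passive_fl", cc)
  expect_equal(trans_abs, 1.5 * base_abs, tolerance = 1e-10)
})

test_that("moment arms are continuous across posture", {
  m <- test_model()
  ang <- seq(-0.4, 0.4, by = 0.05)
  arms <- vapply(ang, function(a) {
    q <- rep(0, 9); q[6] <- a
    moment_arm(m, q, "soleus_r", "ankle_r")
  }, 0)
  expect_true(all(abs(diff(arms)) < 0.01))      # no jumps
  expect_true(all(arms < -0.03))                # plantarflexor throughout
  # dorsiflexor sign for tibialis anterior
  expect_gt(moment_arm(m, rep(0, 9), "tibialis_anterior_r", "ankle_r"), 0.02)
})
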