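# Rigid-body layer: passive joint torques, forward dynamics, energy audits.

test_that("knee ligament torque: dead zone, spring and damper terms", {
  expect_equal(knee_ligament_torque(60, 0), 0)
  expect_equal(knee_ligament_torque(10.0001, 0), 0)
  expect_equal(knee_ligament_torque(119.9999, 0), 0)
  # 5 deg flexion = 5 deg beyond the 10 deg extension limit: 10 Nm toward
  # flexion
  expect_equal(knee_ligament_torque(5, 0), 10)
  # extending at 100 deg/s adds 0.2 * 100 = 20 Nm of damping, same direction
  expect_equal(knee_ligament_torque(5, -100), 30)
  # deep flexion side resists flexion
  expect_equal(knee_ligament_torque(125, 0), -10)
  expect_equal(knee_ligament_torque(125, 50), -20)
  # damper acts only while the spring is engaged
  expect_equal(knee_ligament_torque(60, -500), 0)
})

test_that("AFO torque is linear, restoring, and exactly zero at K = 0", {
  expect_equal(afo_torque(10, 2.6), -26)     # plantarflexing when dorsiflexed
  expect_equal(afo_torque(-5, 8.7), 43.5)    # dorsiflexing when plantarflexed
  expect_equal(afo_torque(37, 0), 0)
  expect_equal(afo_torque(0, 5), 0)
  expect_error(afo_torque(10, -1), ">= 0")
  # linearity
  K <- 3.3
  a <- c(-20, -5, 0, 5, 20)
  expect_equal(afo_torque(a, K), -K * a)
})

test_that("AFO spring is lossless: zero net work over a closed cycle", {
  K <- 5.1
  th <- c(seq(0, 15, by = 0.1), seq(15, -10, by = -0.1),
          seq(-10, 0, by = 0.1)) # closed path in degrees
  tau <- afo_torque(th, K)
  # potential energy K/2 * theta^2 is a state function: net work along any
  # closed path vanishes
  U <- 0.5 * K * th^2
  W <- sum((tau[-1] + tau[-length(tau)]) / 2 * diff(th))
  expect_equal(U[length(U)] - U[1], 0)
  expect_lt(abs(W), 1e-9 * max(U))
})

test_that("free fall follows the closed form within integrator tolerance", {
  m <- test_model()
  # knees flexed inside the ligament dead zone: a contact-free articulated
  # chain under gravity alone is in pure free fall (zero joint
  # accelerations), so the pelvis obeys the point-mass closed form
  st <- model_state(q = c(0, 2, 0, 0.1, 0.6, 0, -0.1, 0.6, 0))
  out <- simulate_passive(m, st, 0.4, method = "fixed")
  n <- nrow(out$q)
  expect_equal(out$q[n, 2], 2 - 0.5 * 9.81 * 0.4^2, tolerance = 2e-3)
  expect_equal(out$q[n, 1], 0, tolerance = 1e-12)
  ref <- simulate_passive(m, st, 0.4, method = "reference")
  expect_equal(unname(ref$q[nrow(ref$q), 2]), 2 - 0.5 * 9.81 * 0.4^2,
               tolerance = 1e-6)
})

test_that("zero velocity and zero net force leave the state unchanged", {
  m <- test_model()
  cm <- afosim:::compile_model(m)
  st <- model_state(q = c(0, 1.2, 0, 0.2, 0.5, 0, -0.2, 0.5, 0))
  d <- afosim:::cpp_dynamics(cm, st$q, st$qd, rep(0, 9), NULL)
  # counteract gravity exactly with the generalized gravity force
  tau_g <- -(d$rhs)
  st2 <- forward_dynamics_step(m, st, 1e-3, tau = tau_g)
  expect_equal(st2$q, st$q, tolerance = 1e-12)
  expect_equal(st2$qd, st$qd, tolerance = 1e-12)
})

test_that("compound-pendulum limit: small-amplitude period within 1%", {
  m <- test_model()
  cm <- afosim:::compile_model(m)
  # all DOF locked except the right hip: the leg swings as a compound
  # pendulum about the hip
  k0 <- segment_kinematics(m, rep(0, 9))
  legs <- c("thigh_r", "shank_r", "foot_r")
  mi <- cm$mass[match(legs, names(m$segments))]
  Ii <- cm$inertia[match(legs, names(m$segments))]
  di <- -k0$com[legs, 2]                      # distance below the hip
  I_hip <- sum(Ii + mi * di^2)
  l_com <- sum(mi * di) / sum(mi)
  T_ref <- 2 * pi * sqrt(I_hip / (sum(mi) * 9.81 * l_com))
  amp <- 0.04
  st <- model_state(q = c(0, 2, 0, amp, rep(0, 5)))
  out <- simulate_passive_locked(m, st, duration = 3 * T_ref,
                                 lock = c(1, 2, 3, 5, 6, 7, 8, 9))
  th <- out$q[, 4]
  tt <- out$time
  # period from successive positive zero crossings
  up <- which(th[-length(th)] < 0 & th[-1] >= 0)
  tc <- tt[up] + th[up] / (th[up] - th[up + 1]) * diff(tt)[1]
  expect_gte(length(tc), 2)
  T_sim <- mean(diff(tc))
  expect_lt(abs(T_sim - T_ref) / T_ref, 0.01)
})

test_that("passive tumble conserves energy (reference integrator audit)", {
  m <- test_model()
  st <- tumble_state()
  E0 <- mechanical_energy(m, st$q, st$qd)
  out <- simulate_passive(m, st, 0.5, method = "reference")
  # the audit presumes a torque-free drop: knees must stay inside the
  # ligament dead zone throughout
  expect_true(all(out$q[, c(5, 8)] * 180 / pi > 10 &
                    out$q[, c(5, 8)] * 180 / pi < 120))
  n <- nrow(out$q)
  E1 <- mechanical_energy(m, out$q[n, ], out$qd[n, ])
  drift <- abs(E1 - E0) / abs(E0) / 0.5
  expect_lt(drift, 1e-4)
})

test_that("bilateral symmetry: mirrored state gives mirrored dynamics", {
  m <- test_model()
  cm <- afosim:::compile_model(m)
  q <- c(0, 1.0, -0.05, 0.3, 0.4, -0.1, -0.2, 0.7, 0.2)
  qd <- c(1, -0.2, 0.1, 0.5, -0.3, 0.2, -0.4, 0.6, -0.1)
  swap <- c(1, 2, 3, 7, 8, 9, 4, 5, 6)
  d1 <- afosim:::cpp_dynamics(cm, q, qd, rep(0, 9), NULL)
  d2 <- afosim:::cpp_dynamics(cm, q[swap], qd[swap], rep(0, 9), NULL)
  expect_equal(d1$qdd[swap], d2$qdd, tolerance = 1e-10)
  # muscle lengths mirror too
  L1 <- muscle_length(m, q); L2 <- muscle_length(m, q[swap])
  expect_equal(unname(L1[1:9]), unname(L2[10:18]), tolerance = 1e-12)
})

test_that("kinematics: R and engine implementations agree", {
  m <- test_model()
  cm <- afosim:::compile_model(m)
  set.seed(14)
  for (i in 1:5) {
    q <- rnorm(9, 0, 0.4); qd <- rnorm(9)
    kr <- segment_kinematics(m, q, qd)
    kc <- afosim:::cpp_kinematics(cm, q, qd)
    expect_equal(kr$com, unname(kc$com), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(kr$com_vel, kc$com_vel, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(kr$theta, as.numeric(kc$theta), tolerance = 1e-12)
  }
})

test_that("trajectory export round-trips through the .sto text dialect", {
  m <- test_model()
  s <- simulate_walk(m, duration = 0.1, record_dt = 0.01)
  f <- tempfile(fileext = ".sto")
  write_sto(s, f)
  d <- read_sto(f)
  expect_equal(d$time, s$traj$time, tolerance = 1e-9)
  expect_equal(d$pelvis_y, s$traj$q[, 2], tolerance = 1e-9)
  expect_equal(d$knee_r, s$traj$q[, 5] * 180 / pi, tolerance = 1e-6)
  unlink(f)
})
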