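# Gait-phase state machine and reflex excitations.

test_that("phase transitions follow the cycle with load gating", {
  th <- c(load_on = 0.15, load_off = 0.05, d_ls = -0.05, d_la = 0.18)
  # landing -> early stance on foot load
  expect_equal(detect_phase("landing", 0.3, 0.5, 0.1, th), "early_stance")
  expect_equal(detect_phase("landing", 0.05, 0.5, 0.1, th), "landing")
  # early -> late stance once the ankle passes behind the pelvis
  expect_equal(detect_phase("early_stance", 0.8, 0, -0.1, th), "late_stance")
  expect_equal(detect_phase("early_stance", 0.8, 0, 0.1, th), "early_stance")
  # late stance -> liftoff on contralateral loading
  expect_equal(detect_phase("late_stance", 0.8, 0.3, -0.2, th), "liftoff")
  # liftoff -> swing when unloaded
  expect_equal(detect_phase("liftoff", 0.01, 0.8, -0.3, th), "swing")
  # swing -> landing when the leg has swung forward
  expect_equal(detect_phase("swing", 0, 0.9, 0.25, th), "landing")
  expect_equal(detect_phase("swing", 0, 0.9, 0.05, th), "swing")
  # ... or on early foot contact: a loaded leg never stays in swing
  expect_equal(detect_phase("swing", 0.4, 0.5, 0.05, th), "landing")
  # an unloaded foot can never sit in a stance phase transition to stance
  expect_equal(detect_phase("landing", 0, 1, 0.3, th), "landing")
})

test_that("phase sequence over a synthetic cycle visits each phase once", {
  th <- c(load_on = 0.15, load_off = 0.05, d_ls = -0.05, d_la = 0.18)
  # scripted one-cycle trajectory of (load, contra_load, dx)
  script <- rbind(
    c(0.5, 0.1, 0.15), c(0.8, 0.0, 0.05),   # early stance
    c(0.9, 0.0, -0.10),                     # -> late stance
    c(0.7, 0.4, -0.20),                     # -> liftoff
    c(0.02, 0.8, -0.25),                    # -> swing
    c(0.0, 0.9, 0.25),                      # -> landing
    c(0.6, 0.2, 0.20))                      # -> early stance again
  ph <- "early_stance"
  seen <- character()
  for (i in seq_len(nrow(script))) {
    ph <- detect_phase(ph, script[i, 1], script[i, 2], script[i, 3], th)
    seen <- c(seen, ph)
  }
  expect_equal(unique(seen),
               c("early_stance", "late_stance", "liftoff", "swing",
                 "landing", "early_stance")[c(1, 2, 3, 4, 5)],
               ignore_attr = TRUE)
  expect_equal(seen[length(seen)], "early_stance")
})

test_that("excitations: zero parameters give zero, arithmetic is exact", {
  m <- test_model()
  v <- controller_vector(m)
  u0 <- muscle_excitations(m, v * 0, "early_stance", "swing")
  expect_true(all(u0 == 0))
  # single muscle with C = 0.05 plus F reflex K_F = 1.2 on a source at
  # normalized force 0.5 -> u = 0.05 + 1.2 * 0.5 = 0.65
  v1 <- v * 0
  v1["r01_tibialis_anterior_const_gain"] <- 0.05
  v1["r04_tibialis_anterior_F_soleus_gain"] <- 1.2
  Fn <- rep(0, 18); Fn[2] <- 0.5           # right soleus normalized force
  u <- muscle_excitations(m, v1, "early_stance", "swing", F_norm = Fn)
  expect_equal(unname(u["tibialis_anterior_r"]), 0.65)
  # the left leg is in swing, where neither entry is active
  expect_equal(unname(u["tibialis_anterior_l"]), 0)
  # L reflex: gain * max(0, l - l0), one-sided
  v2 <- v * 0
  v2["r03_tibialis_anterior_L_tibialis_anterior_gain"] <- 2
  v2["r03_tibialis_anterior_L_tibialis_anterior_l0"] <- 1.0
  Ln <- rep(1, 18); Ln[1] <- 1.1
  uL <- muscle_excitations(m, v2, "swing", "swing", l_norm = Ln)
  expect_equal(unname(uL["tibialis_anterior_r"]), 0.2, tolerance = 1e-12)
  Ln[1] <- 0.9
  uL2 <- muscle_excitations(m, v2, "swing", "swing", l_norm = Ln)
  expect_equal(unname(uL2["tibialis_anterior_r"]), 0)
})

test_that("excitations are clipped to [0, 1] for any gains", {
  m <- test_model()
  tab <- controller_params(m)
  set.seed(5)
  for (i in 1:10) {
    v <- runif(nrow(tab), tab$lower, tab$upper)
    u <- muscle_excitations(m, v, sample(5, 1), sample(5, 1),
                            F_norm = runif(18, 0, 2),
                            l_norm = runif(18, 0.5, 1.6),
                            trunk_pitch = rnorm(1, 0, 0.3),
                            trunk_pitch_vel = rnorm(1))
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("controller output is bit-exact deterministic", {
  m <- test_model()
  v <- controller_vector(m)
  Fn <- runif(18); Ln <- runif(18, 0.8, 1.2)
  u1 <- muscle_excitations(m, v, 2, 4, Fn, Ln, -0.1, 0.2)
  u2 <- muscle_excitations(m, v, 2, 4, Fn, Ln, -0.1, 0.2)
  expect_identical(u1, u2)
})

test_that("parameter vector round-trips through named list and text", {
  m <- test_model()
  v <- controller_vector(m)
  lst <- controller_list(m, v)
  v2 <- controller_vector(m, lst)
  expect_identical(v, v2)
  f <- tempfile()
  write_controller_params(v, f)
  v3 <- read_controller_params(f)
  expect_identical(unname(v), unname(v3[names(v)]))
  expect_identical(names(v), names(v3))
  unlink(f)
})
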