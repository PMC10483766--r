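# Cubic response fits: optimal-stiffness extraction, normalization
# crossings, and the model-as-subject comparison.

test_that("cubic fit recovers the minimum of noiseless quadratic data", {
  K <- stiffness_grid()
  y <- (K - 4)^2 + 3
  sw <- data.frame(stiffness = K, cot = y, ok = TRUE)
  opt <- fit_optimum(sw)
  expect_equal(opt$K_opt, 4, tolerance = 1e-6)
  expect_equal(opt$r, 1, tolerance = 1e-9)
  expect_false(opt$boundary)
  expect_true(opt$reliable)
  # reduction = fitted COT at K = 0 minus fitted COT at the optimum
  expect_equal(opt$reduction, 16, tolerance = 1e-6)
})

test_that("cubic fit with <= 4 distinct points interpolates exactly", {
  K <- c(0, 2, 5, 8)
  y <- c(4.1, 3.2, 3.6, 5.0)
  f <- cubic_fit(K, y)
  expect_lt(max(abs(residuals(f))), 1e-10)
  expect_equal(unname(predict(f, K)), y, tolerance = 1e-10)
})

test_that("noisy quadratic: K_opt matches dense grid search of the fit", {
  for (seed in 1:25) {
    set.seed(seed)
    K <- stiffness_grid()
    y <- (K - 4)^2 + 3 + rnorm(length(K), 0, 0.05)
    sw <- data.frame(stiffness = K, cot = y, ok = TRUE)
    opt <- fit_optimum(sw)
    Kd <- seq(min(K), max(K), length.out = 20001)
    K_grid <- Kd[which.min(predict(opt, Kd))]
    expect_lt(abs(opt$K_opt - K_grid), (max(K) - min(K)) / 20000 + 1e-9)
    expect_lt(abs(opt$K_opt - 4), 0.5)
  }
})

test_that("strictly decreasing response flags a boundary minimum at K_max", {
  K <- stiffness_grid()
  y <- 10 - 0.3 * K
  opt <- fit_optimum(data.frame(stiffness = K, cot = y, ok = TRUE))
  expect_true(opt$boundary)
  expect_equal(opt$K_opt, max(K), tolerance = 1e-8)
})

test_that("fit is invariant to row order and excludes failed rows", {
  set.seed(7)
  K <- stiffness_grid()
  y <- 0.05 * (K - 3.5)^2 + 3.4 + rnorm(length(K), 0, 0.02)
  sw <- data.frame(stiffness = K, cot = y, ok = TRUE)
  o1 <- fit_optimum(sw)
  o2 <- fit_optimum(sw[sample(nrow(sw)), ])
  expect_identical(o1$K_opt, o2$K_opt)
  expect_identical(coef(o1), coef(o2))
  # a failed row with an absurd value must not influence the fit
  sw2 <- rbind(sw, data.frame(stiffness = 4.35, cot = 50, ok = FALSE))
  o3 <- fit_optimum(sw2)
  expect_identical(o1$K_opt, o3$K_opt)
})

test_that("too few rows or unreliable fits are reported as such", {
  K <- c(0, 0.87, 1.74, 2.61)
  expect_error(fit_optimum(data.frame(stiffness = K, cot = K, ok = TRUE)),
               "at least 5")
  # pure noise: low fit correlation must mark the result unreliable
  set.seed(42)
  K <- stiffness_grid()
  repeat {
    y <- rnorm(length(K))
    f <- cubic_fit(K, y)
    if (is.finite(f$r) && f$r <= 0.7) break
  }
  opt <- fit_optimum(data.frame(stiffness = K, cot = y, ok = TRUE))
  expect_false(opt$reliable)
})

test_that("normalization stiffness matches closed-form crossings", {
  K <- stiffness_grid()
  thr <- normative_thresholds()
  # linear trends crossing each threshold at known stiffnesses
  kc <- c(ankle_angle = 2.5, ankle_moment = 3.1, knee_angle = 1.4,
          knee_moment = 2.2)
  sw <- data.frame(
    stiffness = K,
    ankle_angle_max = 17.2 + 4.0 * (kc[["ankle_angle"]] - K),
    ankle_moment_max = 1.17 - 0.2 * (kc[["ankle_moment"]] - K),
    knee_angle_min = 4.2 + 3.0 * (kc[["knee_angle"]] - K),
    knee_moment_min = 0.34 - 0.3 * (kc[["knee_moment"]] - K),
    ok = TRUE)
  ns <- normalization_stiffness(sw)
  for (p in names(kc)) {
    got <- ns$K_norm[ns$parameter == p]
    expect_lt(abs(got - kc[[p]]), 1e-6)
  }
  expect_true(all(ns$crossed))
})

test_that("already-normal parameters need no AFO; never-crossing flags NA", {
  K <- stiffness_grid()
  sw <- data.frame(
    stiffness = K,
    ankle_angle_max = 12 - 0.1 * K,        # below 17.2 already at K = 0
    ankle_moment_max = 0.5 + 0.01 * K,     # never reaches 1.17
    knee_angle_min = 4.2 + 3.0 * (1.4 - K),
    knee_moment_min = 0.34 - 0.3 * (2.2 - K),
    ok = TRUE)
  ns <- normalization_stiffness(sw)
  expect_equal(ns$K_norm[ns$parameter == "ankle_angle"], 0)
  expect_true(is.na(ns$K_norm[ns$parameter == "ankle_moment"]))
  expect_false(ns$crossed[ns$parameter == "ankle_moment"])
})

test_that("compare_optima matches the textbook pooled t statistic", {
  # degenerate cases
  x <- c(3, 4, 5)
  same <- compare_optima(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)
  off <- compare_optima(c(2, 2, 2), c(1, 1, 1))
  expect_equal(off$mean_diff, 1)
  expect_equal(off$p_value, 0)
  # random sets against the direct formula
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(8, 4, 1); b <- rnorm(8, 2.5, 0.8)
    got <- compare_optima(a, b)
    n <- 8
    sp2 <- ((n - 1) * var(a) + (n - 1) * var(b)) / (2 * n - 2)
    t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * 2 / n)
    expect_lt(abs(got$t - t_ref), 1e-9)
    expect_lt(abs(got$p_value -
                    2 * pt(-abs(t_ref), 2 * n - 2)), 1e-12)
    # agreement with stats::t.test as an independent oracle
    tt <- t.test(a, b, var.equal = TRUE)
    expect_lt(abs(got$t - unname(tt$statistic)), 1e-9)
  }
})
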