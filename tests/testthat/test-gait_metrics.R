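# Validation metrics: cycle segmentation, 101-point time normalization,
# cross-correlation, SD-normalized RMSE and 1D SPM inference.

test_that("segment_cycles: n strikes give n - 1 cycles at analytic times", {
  # sinusoid on a pedestal: GRF = 400 * max(0, sin(2 pi t)) crosses 20 N
  # upward once per 1 s period at t = k + asin(0.05) / (2 pi)
  t <- seq(0, 5, by = 1e-3)
  grf <- 400 * pmax(0, sin(2 * pi * t))
  ev <- segment_cycles(grf, t, threshold = 20)
  expect_equal(ev$n_cycles, 4L)
  expected <- 0:4 + asin(20 / 400) / (2 * pi)
  expect_equal(ev$events, expected, tolerance = 1e-5)
  expect_error(segment_cycles(rep(0, 100), seq_len(100)), "complete gait")
})

test_that("time_normalize is exact for uniform and linear inputs", {
  x <- sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(time_normalize(x, seq(0, 1, length.out = 101)), x,
               tolerance = 1e-12)
  ramp <- seq(3, 9, length.out = 57)
  out <- time_normalize(ramp, seq(0, 1.13, length.out = 57))
  expect_equal(out, seq(3, 9, length.out = 101), tolerance = 1e-12)
  expect_equal(out[c(1, 101)], c(3, 9))
  expect_error(time_normalize(1:10, c(1:5, 5, 6:9)), "increasing")
  expect_error(time_normalize(1:3, 1:3), "at least 4")
})

test_that("time_normalize interpolation error obeys the h^2 bound", {
  n <- 41
  t <- seq(0, 1, length.out = n)
  x <- sin(2 * pi * t)
  out <- time_normalize(x, t)
  truth <- sin(2 * pi * seq(0, 1, length.out = 101))
  h <- 1 / (n - 1)
  bound <- (2 * pi)^2 * h^2 / 8      # max |f''| h^2 / 8 for linear interp
  expect_lt(max(abs(out - truth)), bound)
})

test_that("cross-correlation identities", {
  th <- seq(0, 2 * pi, length.out = 101)
  a <- sin(th)
  expect_equal(cross_correlation(a, a), 1, tolerance = 1e-12)
  expect_equal(cross_correlation(a, -a), -1, tolerance = 1e-12)
  # sin vs cos over one period are orthogonal; the shared endpoint sample
  # leaves a tiny O(1/n) correlation
  expect_lt(abs(cross_correlation(sin(th), cos(th))), 0.02)
  th_open <- seq(0, 2 * pi * 100 / 101, length.out = 101)
  expect_lt(abs(cross_correlation(sin(th_open), cos(th_open))), 1e-6)
  expect_warning(r <- cross_correlation(rep(1, 101), a), "zero-variance")
  expect_true(is.na(r))
  # affine invariance up to sign
  expect_equal(cross_correlation(3 * a + 2, a), 1, tolerance = 1e-12)
  expect_equal(cross_correlation(-0.5 * a + 1, a), -1, tolerance = 1e-12)
})

test_that("rmse_sd identities and affine invariance", {
  set.seed(3)
  mean_c <- sin(seq(0, 2 * pi, length.out = 101)) * 10
  sd_c <- 2 + cos(seq(0, 2 * pi, length.out = 101))
  band <- list(mean = mean_c, sd = sd_c)
  expect_equal(rmse_sd(mean_c, band), 0)
  expect_equal(rmse_sd(mean_c + 2 * sd_c, band), 2)          # 95% boundary
  sim <- mean_c + rnorm(101) * sd_c
  direct <- sqrt(mean(((sim - mean_c) / sd_c)^2))
  expect_equal(rmse_sd(sim, band), direct, tolerance = 1e-12)
  # common affine rescaling of sim, mean and SD leaves the metric unchanged
  sc <- 57.3
  expect_equal(rmse_sd(sim * sc, list(mean = mean_c * sc, sd = sd_c * sc)),
               direct, tolerance = 1e-12)
  expect_error(rmse_sd(sim, mean_c, c(0, sd_c[-1])), "positive")
})

test_that("SPM: literally identical groups give a zero field, no clusters", {
  A <- matrix(rep(sin(seq(0, 2 * pi, length.out = 101)), 5), 5, 101,
              byrow = TRUE)
  out <- spm_ttest(A, A)
  expect_true(all(out$t == 0))
  expect_equal(nrow(out$clusters), 0L)
})

test_that("SPM localizes a constructed 5 SD effect at 30-50% GC", {
  bands <- gen_reference_band(band_config(variables = "knee_angle"))
  b <- bands$knee_angle
  A <- gen_cycle_cohort(b, 11, seed = 21)
  offset <- rep(0, 101)
  # smooth bump spanning 30-50% of the gait cycle, 5 SD high
  idx <- 31:51
  offset[idx] <- 5 * b$sd[idx] * sin(seq(0, pi, length.out = length(idx)))
  B <- gen_cycle_cohort(b, 11, seed = 22) +
    matrix(offset, 11, 101, byrow = TRUE)
  out <- spm_ttest(A, B)
  expect_gte(nrow(out$clusters), 1L)
  main <- out$clusters[which.max(out$clusters$end_pct -
                                   out$clusters$start_pct), ]
  expect_gt(main$end_pct, 35); expect_lt(main$start_pct, 45)
  expect_true(main$start_pct >= 25 && main$end_pct <= 55)
})

test_that("SPM type-I error is controlled on null cohorts", {
  bands <- gen_reference_band(band_config(variables = "ankle_angle"))
  b <- bands$ankle_angle
  n_rep <- 200
  fp <- 0L
  for (r in seq_len(n_rep)) {
    A <- gen_cycle_cohort(b, 11, seed = 1000 + 2 * r)
    B <- gen_cycle_cohort(b, 11, seed = 1001 + 2 * r)
    out <- spm_ttest(A, B)
    if (nrow(out$clusters) > 0) fp <- fp + 1L
  }
  # familywise rate <= 0.05 within binomial error (3 sigma)
  expect_lt(fp / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("SPM parametric and permutation thresholds agree within 10%", {
  bands <- gen_reference_band(band_config(variables = "hip_angle"))
  b <- bands$hip_angle
  ratios <- vapply(1:5, function(r) {
    A <- gen_cycle_cohort(b, 11, seed = 300 + 2 * r)
    B <- gen_cycle_cohort(b, 11, seed = 301 + 2 * r)
    out <- spm_ttest(A, B, n_perm = 800, seed = r)
    out$threshold_perm / out$threshold
  }, 0)
  expect_lt(abs(median(ratios) - 1), 0.10)
})

test_that("z-score mode flags a curve far outside the band", {
  bands <- gen_reference_band(band_config(variables = "ankle_moment"))
  b <- bands$ankle_moment
  ok <- spm_zscore(b$mean, b)
  expect_equal(nrow(ok$clusters), 0L)
  bad <- spm_zscore(b$mean + 6 * b$sd, b)
  expect_gt(nrow(bad$clusters), 0L)
})

test_that("validation_report computes R and RMSE/SD per variable", {
  bands <- gen_reference_band(band_config())
  curves <- lapply(bands, function(b) b$mean + 0.5 * b$sd)
  rep <- validation_report(curves, bands)
  expect_equal(nrow(rep), length(bands))
  expect_equal(rep$rmse_sd, rep(0.5, nrow(rep)), tolerance = 1e-12)
  expect_true(all(rep$R > 0.95))
})
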