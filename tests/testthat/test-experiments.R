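# Model variants, the stiffness grid, and the sweep machinery.

test_that("stiffness grid: 11 standard points, exact 0.87 increments", {
  g <- stiffness_grid()
  expect_length(g, 11L)
  expect_equal(g[1], 0)
  expect_equal(diff(g[-1]), rep(0.87, 9), tolerance = 1e-12)
  expect_equal(max(g), 8.7, tolerance = 1e-12)
  expect_true(all(diff(g) > 0))
  ge <- stiffness_grid("extended")
  expect_length(ge, 15L)
  expect_equal(max(ge), 12.18, tolerance = 1e-12)
})

test_that("identity variant returns the base model bit-exactly", {
  m <- test_model()
  v <- model_variant(weakness = 0, passive_scale = 1, mass_factor = 1)
  expect_identical(build_variant(m, v), m)
})

test_that("weakness variant scales only the plantarflexors", {
  m <- test_model()
  w <- build_variant(m, model_variant(weakness = 0.8))
  expect_equal(w$muscles$soleus$fmax, 0.2 * m$muscles$soleus$fmax)
  expect_equal(w$muscles$gastrocnemius$fmax,
               0.2 * m$muscles$gastrocnemius$fmax)
  for (mn in setdiff(names(m$muscles), c("soleus", "gastrocnemius")))
    expect_identical(w$muscles[[mn]], m$muscles[[mn]])
  expect_identical(w$segments, m$segments)
})

test_that("mass variant scales every segment mass, muscle forces untouched", {
  m <- test_model()
  w <- build_variant(m, model_variant(weakness = 0, mass_factor = 1.3))
  for (sn in names(m$segments))
    expect_equal(w$segments[[sn]]$mass, 1.3 * m$segments[[sn]]$mass)
  expect_equal(w$body_mass, 1.3 * m$body_mass)
  for (mn in names(m$muscles))
    expect_equal(w$muscles[[mn]]$fmax, m$muscles[[mn]]$fmax)
  # segment-mass invariant of the compiled model still holds
  expect_silent(afosim:::validate_model(w))
})

test_that("weakness and mass factors commute (disjoint parameters)", {
  m <- test_model()
  a <- build_variant(build_variant(m, model_variant(weakness = 0.6)),
                     model_variant(weakness = 0, mass_factor = 1.1))
  b <- build_variant(build_variant(m, model_variant(weakness = 0,
                                                    mass_factor = 1.1)),
                     model_variant(weakness = 0.6))
  a$variant <- b$variant <- NULL
  expect_equal(a, b, tolerance = 1e-15)
})

test_that("unknown variant levels are rejected", {
  expect_error(model_variant(weakness = 1.2), "weakness")
  expect_error(model_variant(passive_scale = -1), "passive_scale")
  expect_error(model_variant(mass_factor = 0), "mass_factor")
  expect_error(model_variant(speed = -0.5), "speed")
})

test_that("enforced speed is carried into the optimization budget", {
  m <- test_model()
  w <- build_variant(m, model_variant(weakness = 0.8, speed = 1.2))
  expect_equal(w$variant$speed, 1.2)
})

test_that("run_sweep: table shape, caching, and bit-exact resumption", {
  m <- test_model()
  # micro-budget protocol: enough to exercise the machinery
  cfg <- optimizer_config(n_seeds = 1, max_gen = 2, lambda = 4,
                          dt = 5e-4, record_dt = 0.02)
  bud <- simulation_budget(duration = 1.2)
  grid <- c(0, 0.87, 1.74)
  cache <- file.path(tempdir(), paste0("afosim_cache_", Sys.getpid()))
  sw1 <- run_sweep(m, grid, config = cfg, budget = bud, seeds = 1,
                   cache_dir = cache)
  expect_s3_class(sw1, "sweep_table")
  expect_equal(nrow(sw1), 3L)
  expect_equal(sw1$stiffness, grid)
  expect_equal(attr(sw1, "n_simulated"), 3L)
  expect_true(all(c("cot", "speed", "ankle_angle_max", "ankle_moment_max",
                    "knee_angle_min", "knee_moment_min", "ok")
                  %in% names(sw1)))
  # re-run: zero new simulations, bit-exact table
  sw2 <- run_sweep(m, grid, config = cfg, budget = bud, seeds = 1,
                   cache_dir = cache)
  expect_equal(attr(sw2, "n_simulated"), 0L)
  strip <- function(d) as.data.frame(lapply(unclass(d), identity))
  expect_identical(strip(sw1), strip(sw2))
  # a changed protocol must miss the cache
  cfg2 <- optimizer_config(n_seeds = 1, max_gen = 3, lambda = 4,
                           dt = 5e-4, record_dt = 0.02)
  sw3 <- run_sweep(m, grid[1:2], config = cfg2, budget = bud, seeds = 1,
                   cache_dir = cache)
  expect_equal(attr(sw3, "n_simulated"), 2L)
  unlink(cache, recursive = TRUE)
})

test_that("K = 0 sweep row equals an independent no-AFO optimization", {
  m <- test_model()
  cfg <- optimizer_config(n_seeds = 1, max_gen = 2, lambda = 4,
                          dt = 5e-4, record_dt = 0.02)
  bud <- simulation_budget(duration = 1.2)
  sw <- run_sweep(m, c(0, 0.87), config = cfg, budget = bud, seeds = 7)
  solo <- run_cmaes(m, K_afo = 0, config = cfg, budget = bud, seeds = 7)
  expect_equal(sw$cost[1], solo$cost, tolerance = 1e-12)
})

test_that("sweep CSV round-trips", {
  sw <- gen_sweep_table(sweep_config(noise_sd = 0.02), seed = 4)
  f <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, f)
  sw2 <- read_sweep_csv(f)
  expect_equal(as.data.frame(sw2), as.data.frame(sw), tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(c(f, paste0(f, ".json")))
})

test_that("content hash is stable and sensitive", {
  h1 <- afosim:::hash_obj(list(1, "a"))
  h2 <- afosim:::hash_obj(list(1, "a"))
  h3 <- afosim:::hash_obj(list(1, "b"))
  expect_identical(h1, h2)
  expect_false(identical(h1, h3))
})
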