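#' Cost-function weights
#'
#' The composite walking objective:
#' `0.15 * energy cost + 0.1 * head acceleration + 1e8 * falling +
#'  0.1 * unrealistic joint angles + 1e4 * plantarflexor activation above
#'  50%`, plus two speed terms (quadratic shortfall below the minimum
#' walking speed, and quadratic deviation from an enforced speed target
#' when one is set).
#'
#' @param energy,head,fall,joint,activation component weights.
#' @param act_threshold plantarflexor activation threshold (fraction).
#' @param speed_min,speed_target weights of the quadratic speed terms.
#' @return list of class `"cost_weights"`.
#' @export
cost_weights <- function(energy = 0.15, head = 0.1, fall = 1e8,
                         joint = 0.1, activation = 1e4,
                         act_threshold = 0.5, speed_min = 100,
                         speed_target = 10) {
  structure(list(energy = energy, head = head, fall = fall, joint = joint,
                 activation = activation, act_threshold = act_threshold,
                 speed_min = speed_min, speed_target = speed_target),
            class = "cost_weights")
}

#' Simulation budget
#'
#' @param duration bout duration (s, default 10).
#' @param min_speed minimum walking speed (m/s, default 0.3).
#' @param speed enforced speed target (m/s) or `NULL` for self-selected.
#' @return list of class `"simulation_budget"`.
#' @export
simulation_budget <- function(duration = 10, min_speed = 0.3,
                              speed = NULL) {
  stopifnot(duration > 0)
  structure(list(duration = duration, min_speed = min_speed, speed = speed),
            class = "simulation_budget")
}

#' Optimization protocol configuration
#'
#' @param n_seeds independent CMA-ES runs with different random seeds
#'   (default 6; the best is the outcome).
#' @param window plateau window (generations, default 500).
#' @param improve_tol relative improvement threshold of the plateau rule
#'   (default 1e-5, i.e. 0.001%).
#' @param max_gen hard generation cap (default 2000).
#' @param lambda CMA-ES population size (`NULL` = default rule).
#' @param sigma0 initial step size in box-width units.
#' @param dt,record_dt integration and recording steps for objective
#'   evaluations (s).
#' @param transient discarded transient (s).
#' @return list of class `"optimizer_config"`.
#' @export
optimizer_config <- function(n_seeds = 6L, window = 500L,
                             improve_tol = 1e-5, max_gen = 2000L,
                             lambda = NULL, sigma0 = 0.25, dt = 1e-4,
                             record_dt = 0.05, transient = 2) {
  stopifnot(n_seeds >= 1L)
  structure(list(n_seeds = n_seeds, window = window,
                 improve_tol = improve_tol, max_gen = max_gen,
                 lambda = lambda, sigma0 = sigma0, dt = dt,
                 record_dt = record_dt, transient = transient),
            class = "optimizer_config")
}

#' Evaluate the composite walking cost
#'
#' @param sim a [simulate_walk()] result, or its named `summary` vector.
#' @param weights a [cost_weights()].
#' @param budget a [simulation_budget()].
#' @return list with `total` and `components` (named vector of the raw,
#'   unweighted component values) and `weighted` (weighted contributions).
#' @export
evaluate_cost <- function(sim, weights = cost_weights(),
                          budget = simulation_budget()) {
  s <- if (inherits(sim, "sim_result")) sim$summary else sim
  fell <- as.numeric(s[["fell"]] > 0)
  v <- s[["mean_speed"]]
  cot <- s[["cot"]]
  energy <- if (is.finite(cot)) cot else 0
  head <- if (is.finite(s[["head_acc"]])) s[["head_acc"]] else 0
  shortfall <- if (!is.finite(v)) budget$min_speed else
    max(0, budget$min_speed - v)
  target_dev <- if (is.null(budget$speed)) 0 else {
    if (!is.finite(v)) budget$speed else (v - budget$speed)
  }
  comp <- c(energy = energy, head = head, fall = fell,
            joint = s[["joint_viol"]], activation = s[["act_excess"]],
            speed_min = shortfall^2, speed_target = target_dev^2)
  wts <- c(energy = weights$energy, head = weights$head,
           fall = weights$fall, joint = weights$joint,
           activation = weights$activation,
           speed_min = weights$speed_min,
           speed_target = weights$speed_target)
  weighted <- comp * wts
  list(total = sum(weighted), components = comp, weighted = weighted)
}

#' Optimize the walking controller with multi-seed CMA-ES
#'
#' Runs `n_seeds` independent CMA-ES optimizations of the full controller
#' parameter vector (reflex gains, phase thresholds, initial pose) against
#' the composite walking cost, each terminated by the plateau rule or the
#' generation cap, and returns the best seed's result.  Fully reproducible
#' given the seed list.
#'
#' @param model an `afo_model` (a variant built with [build_variant()]
#'   carries its enforced speed into the objective).
#' @param K_afo AFO stiffness (Nm/degree).
#' @param config an [optimizer_config()].
#' @param weights a [cost_weights()].
#' @param budget a [simulation_budget()]; its `speed` is overridden by the
#'   model variant's enforced speed, if any.
#' @param init initial parameter vector (default: configuration initial
#'   values).
#' @param seeds integer seeds (default `1:n_seeds`).
#' @return list of class `"cmaes_walk"`: `params` (best parameter vector),
#'   `cost`, `seed_results` (per-seed summaries), `failed` (TRUE when every
#'   seed's best simulation still fell), `sim` (re-simulated best bout),
#'   `trace` (best seed's convergence trace).
#' @export
run_cmaes <- function(model, K_afo = 0, config = optimizer_config(),
                      weights = cost_weights(),
                      budget = simulation_budget(), init = NULL,
                      seeds = NULL) {
  if (!is.null(model$variant) && !is.null(model$variant$speed))
    budget$speed <- model$variant$speed
  if (is.null(seeds)) seeds <- seq_len(config$n_seeds)
  cm <- compile_model(model)
  tab <- controller_params(model)
  x0 <- if (is.null(init)) stats::setNames(tab$init, tab$name) else init
  x0 <- pmin(pmax(x0, tab$lower), tab$upper)
  opt <- engine_options(duration = budget$duration, dt = config$dt,
                        record_dt = config$record_dt,
                        K_afo = K_afo, transient = config$transient,
                        act_threshold = weights$act_threshold)
  objective <- function(x) {
    out <- cpp_simulate(cm, as.numeric(x), opt)
    ec <- evaluate_cost(out$summary, weights, budget)
    tot <- ec$total
    # shaping inside the search only: among falling candidates, prefer the
    # ones that stay up longer (the reported cost keeps the binary penalty)
    if (ec$components[["fall"]] > 0)
      tot <- tot - weights$fall * 0.6 *
        min(1, out$summary[["t_end"]] / budget$duration)
    tot
  }
  seed_results <- vector("list", length(seeds))
  best <- NULL
  for (i in seq_along(seeds)) {
    r <- cmaes_minimize(objective, x0, tab$lower, tab$upper,
                        sigma0 = config$sigma0, lambda = config$lambda,
                        max_gen = config$max_gen, window = config$window,
                        improve_tol = config$improve_tol,
                        seed = seeds[i])
    seed_results[[i]] <- list(seed = seeds[i], cost = r$f_best,
                              generations = r$generations,
                              converged = r$converged)
    if (is.null(best) || r$f_best < best$f_best) {
      best <- r; best$seed <- seeds[i]
    }
  }
  params <- stats::setNames(best$x_best, tab$name)
  sim <- simulate_walk(model, params, K_afo = K_afo,
                       duration = budget$duration, dt = config$dt,
                       transient = config$transient,
                       act_threshold = weights$act_threshold)
  structure(list(params = params, cost = best$f_best,
                 seed = best$seed, seed_results = seed_results,
                 failed = sim$summary[["fell"]] > 0,
                 sim = sim, trace = best$trace,
                 K_afo = K_afo, budget = budget),
            class = "cmaes_walk")
}

#' @export
print.cmaes_walk <- function(x, ...) {
  cat(sprintf(
    "CMA-ES walking optimization (K_afo = %.2f): best cost %.4g (seed %d)%s\n",
    x$K_afo, x$cost, x$seed, if (x$failed) "  [FAILED: model fell]" else ""))
  s <- x$sim$summary
  if (!x$failed && is.finite(s[["cot"]]))
    cat(sprintf("  speed %.2f m/s, COT %.2f J/kg/m\n", s[["mean_speed"]],
                s[["cot"]]))
  invisible(x)
}
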