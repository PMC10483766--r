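#' AFO stiffness grid
#'
#' The standard sweep: no AFO (stiffness 0) plus ten stiffness levels in
#' exact increments of 0.87 Nm/degree up to 8.7 Nm/degree (11 points).  The
#' extended grid continues to 12.18 Nm/degree for models whose energy
#' response shows no interior optimum on the standard range.
#'
#' @param which `"standard"` (default) or `"extended"`.
#' @return strictly increasing numeric vector of stiffnesses (Nm/degree).
#' @export
stiffness_grid <- function(which = c("standard", "extended")) {
  which <- match.arg(which)
  k <- if (which == "standard") 10L else 14L
  c(0, 0.87 * seq_len(k))
}

# stable content hash of any R object, for cache keys: two independent
# polynomial rolling hashes over the serialized bytes, combined
hash_obj <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h1 <- 17; h2 <- 101
  for (v in b) {
    h1 <- (h1 * 131 + v + 1) %% 2147483629
    h2 <- (h2 * 137 + v + 1) %% 2147483587
  }
  sprintf("%08x%08x", h1, h2)
}

#' Run an AFO stiffness sweep for one model variant
#'
#' One multi-seed CMA-ES walking optimization per stiffness level, followed
#' by steady-state gait summaries.  Per-condition results are cached on
#' disk keyed by a hash of the compiled model, the stiffness, the seeds and
#' the optimization protocol, so an interrupted sweep resumes without
#' recomputation and a completed sweep re-runs with zero new simulations.
#'
#' @param model an `afo_model` (typically from [build_variant()]).
#' @param grid stiffness grid (Nm/degree), default [stiffness_grid()].
#' @param config an [optimizer_config()].
#' @param weights a [cost_weights()].
#' @param budget a [simulation_budget()].
#' @param init initial controller parameters (warm start), optional.
#' @param seeds seeds passed to [run_cmaes()].
#' @param cache_dir directory for per-condition caches; `NULL` disables
#'   caching.
#' @param keep_params return the optimized parameter vectors as an
#'   attribute.
#' @return data frame of class `"sweep_table"`, one row per stiffness:
#'   `stiffness`, `cot`, `speed`, `ankle_angle_max`, `ankle_moment_max`,
#'   `knee_angle_min`, `knee_moment_min`, `cost`, `n_cycles`, `ok` (FALSE
#'   when every seed fell or no steady cycles were found; such rows are
#'   excluded from response fits).  Attributes: `provenance` (seeds,
#'   protocol, config hash), `n_simulated` (conditions actually optimized
#'   in this call, 0 for a fully cached re-run).
#' @export
run_sweep <- function(model, grid = stiffness_grid(),
                      config = optimizer_config(),
                      weights = cost_weights(),
                      budget = simulation_budget(), init = NULL,
                      seeds = NULL, cache_dir = NULL,
                      keep_params = FALSE) {
  stopifnot(all(diff(grid) > 0), all(grid >= 0))
  if (is.null(seeds)) seeds <- seq_len(config$n_seeds)
  cm <- compile_model(model)
  base_key <- hash_obj(list(cm, seeds, unclass(config), unclass(weights),
                            unclass(budget), init))
  n_sim <- 0L
  rows <- vector("list", length(grid))
  params_list <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    K <- grid[i]
    key <- sprintf("%s_K%07.3f", base_key, K)
    cache_file <- if (is.null(cache_dir)) NULL else
      file.path(cache_dir, paste0("sweep_", key, ".rds"))
    res <- NULL
    if (!is.null(cache_file) && file.exists(cache_file))
      res <- readRDS(cache_file)
    if (is.null(res)) {
      fit <- run_cmaes(model, K_afo = K, config = config,
                       weights = weights, budget = budget, init = init,
                       seeds = seeds)
      gs <- gait_summary(fit$sim, model)
      res <- list(row = data.frame(
        stiffness = K,
        cot = fit$sim$summary[["cot"]],
        speed = fit$sim$summary[["mean_speed"]],
        ankle_angle_max = gs$ankle_angle_max,
        ankle_moment_max = gs$ankle_moment_max,
        knee_angle_min = gs$knee_angle_min,
        knee_moment_min = gs$knee_moment_min,
        cost = fit$cost,
        n_cycles = gs$n_cycles,
        ok = !fit$failed && is.finite(fit$sim$summary[["cot"]]) &&
          gs$n_cycles > 0),
        params = fit$params)
      n_sim <- n_sim + 1L
      if (!is.null(cache_file)) {
        dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(res, cache_file)
      }
    }
    rows[[i]] <- res$row
    params_list[[i]] <- res$params
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  attr(out, "provenance") <- list(seeds = seeds, config = unclass(config),
                                  config_hash = base_key,
                                  variant = model$variant)
  attr(out, "n_simulated") <- n_sim
  if (keep_params) attr(out, "params") <- params_list
  out
}

#' Write / read a sweep table as CSV with a provenance sidecar
#'
#' @param sweep a `sweep_table`.
#' @param path CSV path; the provenance (seeds, protocol, config hash) is
#'   written alongside as `<path>.json` when the jsonlite package is
#'   available.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  prov <- attr(sweep, "provenance")
  if (!is.null(prov) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("sweep_table", "data.frame")
  out
}
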