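#' Pearson correlation between two daily series
#'
#' @param series_a,series_b equal-length numeric vectors (length >= 2, each
#'   with nonzero variance).
#' @return the Pearson correlation coefficient in `[-1, 1]`.
#' @export
pcc <- function(series_a, series_b) {
  if (length(series_a) != length(series_b) || length(series_a) < 2L) {
    stop_input("series must have equal length >= 2")
  }
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0) {
    stop_input("correlation undefined: a series has zero variance")
  }
  stats::cor(series_a, series_b)
}

#' Calibration specification
#'
#' Controls the coordinate-descent fit of the model to an observed daily
#' border-crossing series. The memory-retention parameter is excluded from
#' the default free set: literature recommendations exist for it, so it is
#' fixed unless explicitly requested.
#'
#' @param free_parameters subset of `c("tau", "delta", "theta", "v", "Q",
#'   "I_hi", "I_lo")` to fit (default `c("v", "Q")`).
#' @param bounds named list of `c(lo, hi)` per free parameter.
#' @param grid_points grid values per line search (default 7; threshold
#'   parameters use the integer grid within bounds).
#' @param replicates simulation replicates averaged per objective
#'   evaluation (default 3). The same replicate seed stream is reused
#'   across all evaluations (common random numbers), making the objective a
#'   deterministic function of the parameters.
#' @param max_cycles maximum full coordinate cycles (default 3).
#' @param tolerance relative loss improvement below which a full cycle
#'   stops the search (default 1e-3).
#' @param objective `"rmse"` (default) or `"one_minus_pcc"`, computed on
#'   smoothed series.
#' @param smoothing_window moving-average window in days applied to both
#'   series before the loss (default 7).
#' @param seed base seed for the replicate stream.
#' @return an object of class `calibration_spec`.
#' @export
calibration_spec <- function(free_parameters = c("v", "Q"),
                             bounds = list(v = c(0.05, 2), Q = c(10, 1e6)),
                             grid_points = 7L,
                             replicates = 3L,
                             max_cycles = 3L,
                             tolerance = 1e-3,
                             objective = c("rmse", "one_minus_pcc"),
                             smoothing_window = 7L,
                             seed = 1L) {
  allowed <- c("tau", "delta", "theta", "v", "Q", "I_hi", "I_lo")
  if (!all(free_parameters %in% allowed)) {
    stop_config("free_parameters must be among ",
                paste(allowed, collapse = ", "))
  }
  for (nm in free_parameters) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2L || b[1] >= b[2]) {
      stop_config("bounds for ", nm, " must be c(lo, hi) with lo < hi")
    }
  }
  if (replicates < 1L) stop_config("replicates must be >= 1")
  if (grid_points < 2L) stop_config("grid_points must be >= 2")
  if (max_cycles < 1L) stop_config("max_cycles must be >= 1")
  objective <- match.arg(objective)
  structure(list(free_parameters = free_parameters, bounds = bounds,
                 grid_points = as.integer(grid_points),
                 replicates = as.integer(replicates),
                 max_cycles = as.integer(max_cycles),
                 tolerance = tolerance, objective = objective,
                 smoothing_window = as.integer(smoothing_window),
                 seed = as.integer(seed)),
            class = "calibration_spec")
}

# Average daily refugee series over replicate runs on a fixed day axis.
replicate_mean_series <- function(params, sim_inputs, spec, days) {
  acc <- numeric(length(days))
  for (r in seq_len(spec$replicates)) {
    traj <- run_simulation(sim_inputs$population, sim_inputs$events,
                           params, sim_inputs$horizon,
                           seed = spec$seed + r,
                           graph = sim_inputs$graph)
    s <- daily_series(traj, type_filter = "refugee", days = days)
    acc <- acc + s$count
  }
  acc / spec$replicates
}

#' Calibration loss for a parameter vector
#'
#' Simulates `spec$replicates` trajectories with a fixed seed stream,
#' averages the daily refugee series, applies the smoothing window to both
#' the simulated and observed series, and returns the RMSE (default) or
#' `1 - PCC` between them.
#'
#' @param params a [migration_params()] object.
#' @param observed data frame with columns `day` and `count` covering the
#'   crossing-day range implied by `sim_inputs$horizon` and the decision
#'   lag.
#' @param sim_inputs list with `population`, `events`, `graph`, `horizon`.
#' @param spec a [calibration_spec()].
#' @return scalar loss (>= 0).
#' @export
calibration_objective <- function(params, observed, sim_inputs, spec) {
  if (!all(c("day", "count") %in% names(observed))) {
    stop_input("observed must have columns day, count")
  }
  days <- seq(1L + params$decision_lag,
              sim_inputs$horizon + params$decision_lag)
  if (!setequal(observed$day, days)) {
    stop_input("observed day range does not match the simulated range ",
               min(days), "..", max(days))
  }
  obs <- observed$count[match(days, observed$day)]
  sim <- replicate_mean_series(params, sim_inputs, spec, days)
  obs_s <- moving_average(obs, spec$smoothing_window)
  sim_s <- moving_average(sim, spec$smoothing_window)
  if (spec$objective == "rmse") {
    sqrt(mean((sim_s - obs_s)^2))
  } else {
    1 - pcc(sim_s, obs_s)
  }
}

#' Fit free parameters by coordinate descent
#'
#' Cycles through the free parameters; for each, evaluates the objective on
#' a bounded grid (integer grid for the peer thresholds) holding the others
#' fixed, and accepts the grid argmin when it does not increase the loss
#' (ties broken towards the smallest parameter value). Stops when a full
#' cycle improves the loss by less than `spec$tolerance` (relative) or
#' after `spec$max_cycles` cycles. The loss trace is nonincreasing by
#' construction.
#'
#' @param objective_fn function(params) -> loss; typically a closure over
#'   [calibration_objective()].
#' @param params starting [migration_params()].
#' @param spec a [calibration_spec()].
#' @return list with `params` (fitted), `loss`, `trace` (loss after each
#'   accepted update, starting at the initial loss), `evaluations`, and
#'   `converged`.
#' @export
coordinate_descent <- function(objective_fn, params, spec) {
  integer_params <- c("I_hi", "I_lo")
  current <- objective_fn(params)
  trace <- current
  n_eval <- 1L
  converged <- FALSE
  for (cycle in seq_len(spec$max_cycles)) {
    cycle_start <- current
    for (nm in spec$free_parameters) {
      b <- spec$bounds[[nm]]
      grid <- seq(b[1], b[2], length.out = spec$grid_points)
      if (nm %in% integer_params) grid <- unique(round(grid))
      # keep the threshold ordering I_lo <= I_hi feasible
      if (nm == "I_lo") grid <- grid[grid <= params$I_hi]
      if (nm == "I_hi") grid <- grid[grid >= params$I_lo]
      if (length(grid) == 0L) next
      losses <- vapply(grid, function(val) {
        # grid points outside the parameter domain are infeasible
        cand <- tryCatch(
          update_params(params, stats::setNames(list(val), nm)),
          displaceabm_config_error = function(e) NULL)
        if (is.null(cand)) Inf else objective_fn(cand)
      }, 0.0)
      n_eval <- n_eval + length(grid)
      best <- which.min(losses)          # ties -> smallest grid value
      if (losses[best] <= current) {
        params <- update_params(params,
                                stats::setNames(list(grid[best]), nm))
        current <- losses[best]
      }
      trace <- c(trace, current)
    }
    if (cycle_start - current < spec$tolerance * max(cycle_start, 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(params = params, loss = current, trace = trace,
       evaluations = n_eval, converged = converged)
}

#' Calibrate the model against an observed daily series
#'
#' Convenience wrapper binding [calibration_objective()] into
#' [coordinate_descent()] and reporting the final smoothed-series Pearson
#' correlation alongside the fit.
#'
#' @param population,events,graph simulation inputs.
#' @param observed data frame with columns `day`, `count`.
#' @param params starting [migration_params()].
#' @param horizon simulated days.
#' @param spec a [calibration_spec()].
#' @return list with `params`, `loss`, `trace`, `converged`,
#'   `evaluations`, `pcc` (smoothed fitted-vs-observed correlation) and
#'   `spec`.
#' @export
calibrate <- function(population, events, observed, params, horizon,
                      spec = calibration_spec(), graph = NULL) {
  if (is.null(graph)) graph <- build_neighborhood(population$households)
  sim_inputs <- list(population = population, events = events,
                     graph = graph, horizon = horizon)
  fit <- coordinate_descent(function(p) {
    calibration_objective(p, observed, sim_inputs, spec)
  }, params, spec)
  days <- seq(1L + fit$params$decision_lag,
              horizon + fit$params$decision_lag)
  sim <- replicate_mean_series(fit$params, sim_inputs, spec, days)
  obs <- observed$count[match(days, observed$day)]
  fit$pcc <- tryCatch(
    pcc(moving_average(sim, spec$smoothing_window),
        moving_average(obs, spec$smoothing_window)),
    error = function(e) NA_real_)
  fit$spec <- spec
  fit
}
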