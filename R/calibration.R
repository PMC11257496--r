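# Threshold calibration: relative-error fitness against reference time
# series and multi-swarm particle swarm optimisation.

#' Names of the calibrated threshold parameters
#' @export
calibrated_parameters <- function() {
  c("PDGFf", "SNCthr", "MMPthr", "ECMthr", "INFthr", "CSF1thr")
}

#' Relative-error fitness between a simulated and a reference time series
#'
#' Sum over observables and timepoints of `|sim - ref| / max(ref, eps)`.
#' Lower is better; identical series score 0. The simulation is resampled to
#' the reference timestamps by nearest sample.
#'
#' @param sim Time-series tibble of the candidate run.
#' @param ref Reference set (tibble with `time_mcs` and observable columns).
#' @param observables Columns compared; defaults to all non-time columns of
#'   `ref` that are present in `sim`.
#' @param eps Floor protecting relative error against zero references.
#' @param weights Optional named per-observable weights (default 1).
#' @return Non-negative scalar.
#' @export
fitness <- function(sim, ref,
                    observables = NULL, eps = 1, weights = NULL) {
  tcols <- c("time_mcs", "time_days")
  if (is.null(observables))
    observables <- setdiff(intersect(names(ref), names(sim)), tcols)
  if (!length(observables)) stop("no shared observables to compare")
  missing <- setdiff(observables, names(sim))
  if (length(missing))
    stop("simulation lacks observable(s): ", paste(missing, collapse = ", "))
  nearest <- vapply(ref$time_mcs, function(t)
    which.min(abs(sim$time_mcs - t)), integer(1))
  total <- 0
  for (ob in observables) {
    w <- if (!is.null(weights) && ob %in% names(weights)) weights[[ob]] else 1
    rv <- ref[[ob]]
    sv <- sim[[ob]][nearest]
    total <- total + w * sum(abs(sv - rv) / pmax(rv, eps))
  }
  total
}

#' Multi-swarm particle swarm optimisation
#'
#' Standard PSO velocity/position updates with box clamping:
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`, `x <- clamp(x + v)`.
#' Each swarm tracks its own global best independently; the best across
#' swarms is returned. Non-finite objective values cause the particle to be
#' re-sampled within bounds.
#'
#' @param objective Function mapping a parameter vector to a scalar.
#' @param bounds Two-row matrix (`lower`, `upper`) with one column per
#'   parameter.
#' @param n_swarms,n_particles,n_iterations Swarm topology and budget.
#' @param inertia,cognitive,social PSO coefficients.
#' @param seed Random seed.
#' @return List with `par` (best position), `value` (best fitness),
#'   `best_iteration`, `trace` (tibble: swarm, iteration, best fitness so
#'   far), and `swarm_best` (per-swarm best positions/fitnesses).
#' @export
pso_search <- function(objective, bounds, n_swarms = 2L, n_particles = 10L,
                       n_iterations = 30L, inertia = 0.72,
                       cognitive = 1.49, social = 1.49, seed = 1L) {
  stopifnot(nrow(bounds) == 2, all(is.finite(bounds)),
            n_swarms >= 1, n_particles >= 1, n_iterations >= 0,
            inertia > 0, cognitive > 0, social > 0)
  lo <- bounds[1, ]; hi <- bounds[2, ]
  d <- length(lo)
  set.seed(seed)
  LO <- matrix(lo, n_particles, d, byrow = TRUE)
  HI <- matrix(hi, n_particles, d, byrow = TRUE)
  eval_safe <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) NA_real_ else v
  }
  trace <- list()
  swarm_best <- list()
  for (s in seq_len(n_swarms)) {
    X <- matrix(stats::runif(n_particles * d, lo, hi), n_particles, d,
                byrow = TRUE)
    V <- matrix(stats::runif(n_particles * d, -(hi - lo), hi - lo),
                n_particles, d, byrow = TRUE) * 0.1
    fit <- apply(X, 1, eval_safe)
    while (anyNA(fit)) {  # re-sample non-finite evaluations
      bad <- which(is.na(fit))
      X[bad, ] <- matrix(stats::runif(length(bad) * d, lo, hi),
                         length(bad), d, byrow = TRUE)
      fit[bad] <- apply(X[bad, , drop = FALSE], 1, eval_safe)
    }
    P <- X; pfit <- fit
    g <- which.min(pfit)
    gx <- P[g, ]; gfit <- pfit[g]; git <- 0L
    trace[[length(trace) + 1L]] <-
      tibble::tibble(swarm = s, iteration = 0L, best = gfit)
    if (n_iterations > 0) {
      for (it in seq_len(n_iterations)) {
        r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
        r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
        V <- inertia * V + cognitive * r1 * (P - X) +
          social * r2 * (matrix(gx, n_particles, d, byrow = TRUE) - X)
        X <- pmin(pmax(X + V, LO), HI)
        fit <- apply(X, 1, eval_safe)
        bad <- which(is.na(fit))
        if (length(bad)) {
          X[bad, ] <- matrix(stats::runif(length(bad) * d, lo, hi),
                             length(bad), d, byrow = TRUE)
          fit[bad] <- apply(X[bad, , drop = FALSE], 1, eval_safe)
          fit[is.na(fit)] <- Inf
        }
        imp <- fit < pfit
        P[imp, ] <- X[imp, ]; pfit[imp] <- fit[imp]
        g <- which.min(pfit)
        if (pfit[g] < gfit) { gfit <- pfit[g]; gx <- P[g, ]; git <- it }
        trace[[length(trace) + 1L]] <-
          tibble::tibble(swarm = s, iteration = it, best = gfit)
      }
    }
    swarm_best[[s]] <- list(par = gx, value = gfit, best_iteration = git)
  }
  vals <- vapply(swarm_best, function(b) b$value, numeric(1))
  best <- swarm_best[[which.min(vals)]]
  names(best$par) <- colnames(bounds)
  list(par = best$par, value = best$value,
       best_iteration = best$best_iteration,
       trace = do.call(rbind, trace), swarm_best = swarm_best)
}

#' Generate a reference trajectory fixture from a known parameter set
#'
#' Runs the simulator and returns its sampled observables as a reference set
#' for calibration and parameter-recovery testing (simulate with known
#' parameters, perturb, recover).
#'
#' @param params Model parameters (the "true" parameter set).
#' @param scenario A [scenario_config()] or scenario name.
#' @param seed Seed of the fixture run.
#' @param scale `"full"` (scenario lattice as given) or `"reduced"`
#'   (halved lattice sides).
#' @return A tibble with the sampling grid and the observables
#'   fibroblasts, myofibroblasts, macrophages, senescent, ECM volume and
#'   wound closure.
#' @export
generate_reference_fixture <- function(params = default_params(),
                                       scenario = "healthy", seed = 1L,
                                       scale = c("full", "reduced")) {
  scale <- match.arg(scale)
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  if (scale == "reduced") scenario$lattice <- pmax(scenario$lattice %/% 2L, 32L)
  out <- run_simulation(scenario, seed = seed, params = params)
  out$timeseries[, c("time_mcs", "time_days", "fibroblasts",
                     "myofibroblasts", "macrophages", "senescent",
                     "ecm_volume", "wound_closure")]
}

#' Objective function for threshold calibration
#'
#' Maps a vector over the six free thresholds (see
#' [calibrated_parameters()]) to the relative-error fitness of a simulation
#' run against a reference set. Each evaluation uses the same fixed seed to
#' reduce noise-induced thrashing of the swarm.
#'
#' @param ref Reference set (e.g. from [generate_reference_fixture()]).
#' @param scenario Scenario for candidate runs (lattice/days set the scale).
#' @param params Base parameters; candidate thresholds are substituted in.
#' @param eval_seed Fixed seed used for every candidate evaluation.
#' @return `function(x)` suitable for [pso_search()].
#' @export
threshold_objective <- function(ref, scenario, params = default_params(),
                                eval_seed = 99L) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  pn <- calibrated_parameters()
  function(x) {
    pr <- params
    for (i in seq_along(pn)) pr$rules[[pn[i]]] <- x[i]
    out <- run_simulation(scenario, seed = eval_seed, params = pr)
    fitness(out$timeseries, ref)
  }
}
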