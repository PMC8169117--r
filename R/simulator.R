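#' Simulation settings
#'
#' Container for the ensemble-simulation controls. Defaults follow the
#' reference numerical protocol: Heun integration with `dt = 0.1`, all
#' simulations stopped at time 1000, and a germination threshold of 1.0 on
#' the Integrator. The threshold value is not part of the published
#' parameter table; 1.0 lies between the post-rise germination-branch
#' Integrator state (~0.06 at defaults) and the pre-rise high-Integrator
#' initial state (~23), see [check_threshold_bracketing()].
#'
#' @param dt integration step.
#' @param t_final stop time.
#' @param n_seeds ensemble size.
#' @param germination_threshold Integrator level below which a seed is
#'   tagged germinated (checked after each full step).
#' @param rng_seed integer master seed; per-seed substreams are derived
#'   from it, so results are independent of simulation order.
#' @param record_trajectories logical; reserved for trajectory recording.
#' @param base optional settings object to modify.
#' @return A `simulation_settings` object.
#' @export
simulation_settings <- function(dt = 0.1, t_final = 1000, n_seeds = 1000,
                                germination_threshold = 1, rng_seed = 1L,
                                record_trajectories = FALSE, base = NULL) {
  s <- list(dt = dt, t_final = t_final, n_seeds = n_seeds,
            germination_threshold = germination_threshold,
            rng_seed = rng_seed, record_trajectories = record_trajectories)
  if (!is.null(base)) {
    stopifnot(inherits(base, "simulation_settings"))
    given <- names(as.list(match.call())[-1])
    given <- setdiff(given, "base")
    s <- utils::modifyList(unclass(base), s[given])
  }
  if (!(s$dt > 0)) stop("dt must be > 0")
  if (!(s$t_final > s$dt)) stop("t_final must exceed dt")
  if (!(s$n_seeds >= 1)) stop("n_seeds must be >= 1")
  if (!(s$germination_threshold > 0)) stop("germination_threshold must be > 0")
  s$n_seeds <- as.integer(s$n_seeds)
  s$rng_seed <- as.numeric(s$rng_seed)
  structure(s, class = "simulation_settings")
}

#' Initial state of a seed
#'
#' The deterministic pre-sowing fixed point with the highest Integrator
#' value (computed with the Z-coupled GA production term absent,
#' `beta_GA_Z * Z = 0`), with Z itself started at 0 so that it relaxes
#' towards `beta_Z / v_Z` during the simulation and produces the
#' sowing-induced rise in GA production. Exogenous-dose simulations use
#' the same initial state as untreated seeds, so no dose argument is taken.
#'
#' @param p an [model_parameters()] object.
#' @return A [system_state()] at `t = 0`.
#' @export
initial_state <- function(p) {
  fp <- solve_fixed_points(p, z_value = 0)
  fp <- fp[fp$stability == "stable", , drop = FALSE]
  if (!nrow(fp)) stop("no stable pre-rise fixed point")
  top <- fp[which.max(fp$I), ]
  system_state(ABA = top$ABA, GA = top$GA, I = top$I, Z = 0, t = 0)
}

#' One stochastic Heun step (R reference implementation)
#'
#' Predictor-corrector update of the chemical Langevin equations under the
#' Ito interpretation: the predictor uses drift and diffusion evaluated at
#' the current state; the corrector averages the drift between the current
#' and predictor states while reusing the same noise increment; any
#' negative component is clamped to zero (absorptive barrier) after both
#' stages. This R version mirrors the compiled ensemble integrator and is
#' used for its verification.
#'
#' @param state a [system_state()].
#' @param p an [model_parameters()] object.
#' @param dose an [exogenous_dose()].
#' @param dt step size.
#' @param noise_increments 4 Gaussian increments with variance `dt`
#'   (named or ordered ABA, GA, I, Z); defaults to zero (deterministic step).
#' @return The updated [system_state()] with time advanced by `dt`.
#' @export
heun_step <- function(state, p, dose = exogenous_dose(), dt,
                      noise_increments = c(0, 0, 0, 0)) {
  stopifnot(dt > 0, length(noise_increments) == 4)
  x <- .as_state(state)
  a0 <- drift(x, p, dose)
  b0 <- diffusion_amplitude(x, p, dose)
  dW <- as.numeric(noise_increments)
  xp <- pmax(x + a0 * dt + b0 * dW, 0)
  a1 <- drift(xp, p, dose)
  xn <- pmax(x + 0.5 * (a0 + a1) * dt + b0 * dW, 0)
  if (any(!is.finite(xn)))
    stop("non-finite update in component(s): ",
         paste(names(xn)[!is.finite(xn)], collapse = ", "))
  system_state(xn[["ABA"]], xn[["GA"]], xn[["I"]], xn[["Z"]],
               t = attr(state, "t") %||% 0 + dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an ensemble of seeds
#'
#' Integrates the chemical Langevin equations independently for each seed
#' from [initial_state()] and records the first time the Integrator drops
#' below the germination threshold (step-end convention, no within-step
#' interpolation). Seeds with no crossing by `t_final` are censored and are
#' not considered germinated. Per-seed noise streams are derived from
#' `settings$rng_seed` and the seed index only, so results do not depend on
#' the order of evaluation or on R's global RNG state.
#'
#' @param p an [model_parameters()] object.
#' @param dose an [exogenous_dose()].
#' @param settings a [simulation_settings()] object.
#' @param init optional precomputed initial [system_state()] (to avoid
#'   re-solving the pre-rise fixed point in scans).
#' @return An `ensemble_result`: list with `times` (per-seed germination
#'   time, `NA` for censored), `germination_times` (germinated seeds only),
#'   `n_censored`, `n_seeds` and a `provenance` record.
#' @export
simulate_ensemble <- function(p, dose = exogenous_dose(),
                              settings = simulation_settings(),
                              init = NULL) {
  stopifnot(inherits(settings, "simulation_settings"))
  if (is.null(init)) init <- initial_state(p)
  x0 <- .as_state(init)
  times <- .simulate_ensemble_cpp(unclass(p), dose$ABA, dose$GA, unname(x0),
                                  settings$dt, settings$t_final,
                                  settings$germination_threshold,
                                  settings$n_seeds, settings$rng_seed,
                                  use_noise = TRUE)
  structure(list(
    times = times,
    germination_times = times[!is.na(times)],
    n_censored = sum(is.na(times)),
    n_seeds = settings$n_seeds,
    provenance = list(parameters = unclass(p),
                      dose = unclass(dose),
                      settings = unclass(settings),
                      initial_state = as.list(x0),
                      package = "seedswitch",
                      version = as.character(utils::packageVersion("seedswitch")))
  ), class = "ensemble_result")
}

#' Simulate a single seed
#'
#' @inheritParams simulate_ensemble
#' @return The germination time, or `NA` if censored.
#' @export
simulate_seed <- function(p, dose = exogenous_dose(),
                          settings = simulation_settings(), init = NULL) {
  s <- simulation_settings(base = settings, n_seeds = 1L)
  simulate_ensemble(p, dose, s, init = init)$times[1]
}

#' @export
print.ensemble_result <- function(x, ...) {
  n_g <- length(x$germination_times)
  cat(sprintf("ensemble of %d seeds: %d germinated (%.1f%%), %d censored\n",
              x$n_seeds, n_g, 100 * n_g / x$n_seeds, x$n_censored))
  if (n_g)
    cat(sprintf("  germination times: mean %.2f, sd %.2f, range [%.1f, %.1f]\n",
                mean(x$germination_times), stats::sd(x$germination_times),
                min(x$germination_times), max(x$germination_times)))
  invisible(x)
}

#' Deterministic trajectory and threshold-crossing time
#'
#' Noiseless Heun integration (second-order deterministic ODE integration)
#' from a given state; returns the first step-end time the Integrator is
#' below threshold, or `NA`.
#'
#' @inheritParams simulate_ensemble
#' @param init initial state (default [initial_state()]).
#' @return list with `crossing_time` and the final `state`.
#' @export
deterministic_crossing_time <- function(p, dose = exogenous_dose(),
                                        settings = simulation_settings(),
                                        init = NULL) {
  if (is.null(init)) init <- initial_state(p)
  x0 <- .as_state(init)
  t <- .simulate_ensemble_cpp(unclass(p), dose$ABA, dose$GA, unname(x0),
                              settings$dt, settings$t_final,
                              settings$germination_threshold,
                              1L, 0, use_noise = FALSE)
  t[1]
}

#' Record one stochastic (or deterministic) trajectory
#'
#' @inheritParams simulate_ensemble
#' @param init initial state.
#' @param n_steps number of Heun steps to record.
#' @param stream substream index (distinct trajectories from one seed).
#' @param use_noise logical; `FALSE` gives the deterministic limit.
#' @return data frame with columns `t`, `ABA`, `GA`, `I`, `Z`.
#' @export
simulate_trajectory <- function(p, dose = exogenous_dose(),
                                init = initial_state(p),
                                dt = 0.1, n_steps = 10000, rng_seed = 1,
                                stream = 0L, use_noise = TRUE) {
  x0 <- .as_state(init)
  m <- .simulate_trajectory_cpp(unclass(p), dose$ABA, dose$GA, unname(x0),
                                dt, as.integer(n_steps), as.numeric(rng_seed),
                                use_noise, as.integer(stream))
  out <- as.data.frame(m)
  names(out) <- c("t", "ABA", "GA", "I", "Z")
  out
}

#' Check the germination-threshold bracketing
#'
#' Asserts that the chosen germination threshold lies strictly between the
#' post-rise germination-branch stable Integrator state and the pre-rise
#' high-Integrator initial state, the calibration under which the
#' first-passage reading of germination is meaningful.
#'
#' @param p an [model_parameters()] object.
#' @param threshold germination threshold to check.
#' @return Invisibly `TRUE`; error if the bracketing fails.
#' @export
check_threshold_bracketing <- function(p, threshold = 1) {
  post <- solve_fixed_points(p, z_value = p$beta_Z / p$v_Z)
  post_stable <- post$I[post$stability == "stable"]
  pre_high <- initial_state(p)[["I"]]
  if (!(min(post_stable) < threshold))
    stop("threshold ", threshold, " is not above the post-rise germination ",
         "branch (I = ", format(min(post_stable)), ")")
  if (!(pre_high > threshold))
    stop("threshold ", threshold, " is not below the pre-rise high-Integrator ",
         "state (I = ", format(pre_high), ")")
  invisible(TRUE)
}
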