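#' Right-hand side of the scalar fixed-point equation
#'
#' At steady state the ABA and GA equations are solved explicitly in terms
#' of the Integrator concentration `I`:
#' `ABA0(I) = (beta_ABA + f_ABA(I)) / v_ABA`,
#' `GA0(I) = (beta_GA + beta_GA_Z * z + g_GA(I)) / v_GA`,
#' and substituting into the Integrator equation gives the scalar condition
#' `I = (beta_I + f_I(ABA0 + ABA_exo)) / (v_I + f_I_GA(GA0 + GA_exo))`.
#' This helper evaluates the right-hand side for vectors of `I`.
#' @noRd
.fp_rhs <- function(I, p, z_value, dose) {
  ABA0 <- (p$beta_ABA + hill_increasing(I, p$C_ABA_I, p$theta_ABA_I, p$h)) / p$v_ABA
  GA0  <- (p$beta_GA + p$beta_GA_Z * z_value +
             hill_decreasing(I, p$C_GA_I, p$theta_GA_I, p$h)) / p$v_GA
  (p$beta_I + hill_increasing(ABA0 + dose$ABA, p$C_I_ABA, p$theta_I_ABA, p$h)) /
    (p$v_I + hill_increasing(GA0 + dose$GA, p$C_I_GA, p$theta_I_GA, p$h))
}

#' Deterministic fixed points of the germination switch
#'
#' Finds every steady state of the deterministic model for a given value of
#' the sowing factor Z. Candidate roots of the scalar Integrator equation
#' are bracketed by sign changes on a geometric grid and refined by
#' bracketed root-finding; stability is assessed from the sign of the
#' reduced Integrator dynamics (`dI/dt` with ABA and GA slaved to their
#' steady-state expressions) just below and above each root, so stable and
#' unstable roots alternate.
#'
#' `z_value = 0` gives the pre-sowing ("pre-rise") system in which the
#' Z-coupled GA production term is absent; `z_value = beta_Z / v_Z` gives
#' the post-sowing ("post-rise") system.
#'
#' @param p an [model_parameters()] object.
#' @param z_value steady-state Z concentration feeding GA production.
#' @param dose an [exogenous_dose()].
#' @param tol absolute tolerance on the scalar equation residual.
#' @param I_range search interval for the Integrator concentration.
#' @param points_per_decade bracketing grid density.
#' @return A data frame of class `fixed_points` with columns `I`, `ABA`,
#'   `GA`, `Z`, `stability` ("stable"/"unstable"), `residual`, ordered by
#'   increasing `I`. Empty (with a warning) if no root is detected.
#' @export
solve_fixed_points <- function(p, z_value = p$beta_Z / p$v_Z,
                               dose = exogenous_dose(),
                               tol = 1e-10,
                               I_range = c(1e-6, 1e4),
                               points_per_decade = 50) {
  stopifnot(tol > 0, length(I_range) == 2, I_range[1] > 0,
            I_range[2] > I_range[1], z_value >= 0)
  n <- ceiling(log10(I_range[2] / I_range[1]) * points_per_decade) + 1
  grid <- exp(seq(log(I_range[1]), log(I_range[2]), length.out = n))
  G <- .fp_rhs(grid, p, z_value, dose) - grid

  roots <- numeric(0)
  sgn <- sign(G)
  idx <- which(sgn[-1] * sgn[-n] < 0)
  for (i in idx) {
    r <- stats::uniroot(function(I) .fp_rhs(I, p, z_value, dose) - I,
                        lower = grid[i], upper = grid[i + 1],
                        tol = .Machine$double.eps^0.75)$root
    roots <- c(roots, r)
  }
  roots <- c(roots, grid[sgn == 0])
  roots <- sort(unique(roots))
  if (!length(roots)) {
    warning("no fixed point detected on the bracketing grid; ",
            "degenerate parameterization?")
    out <- data.frame(I = numeric(0), ABA = numeric(0), GA = numeric(0),
                      Z = numeric(0), stability = character(0),
                      residual = numeric(0))
    class(out) <- c("fixed_points", class(out))
    return(out)
  }

  # stability from the sign of dI/dt in the intervals between roots;
  # probe at geometric midpoints to stay clear of neighbouring roots
  bounds <- c(I_range[1] / 2, roots, I_range[2] * 2)
  probe <- sqrt(bounds[-length(bounds)] * bounds[-1])
  sign_at <- sign(.fp_rhs(probe, p, z_value, dose) - probe)
  stability <- vapply(seq_along(roots), function(j) {
    if (sign_at[j] > 0 && sign_at[j + 1] < 0) "stable" else "unstable"
  }, character(1))

  residual <- abs(.fp_rhs(roots, p, z_value, dose) - roots)
  if (any(residual > tol))
    warning("fixed-point residual above tolerance: max ",
            format(max(residual)))
  ABA0 <- (p$beta_ABA + hill_increasing(roots, p$C_ABA_I, p$theta_ABA_I, p$h)) / p$v_ABA
  GA0  <- (p$beta_GA + p$beta_GA_Z * z_value +
             hill_decreasing(roots, p$C_GA_I, p$theta_GA_I, p$h)) / p$v_GA
  out <- data.frame(I = roots, ABA = ABA0, GA = GA0, Z = z_value,
                    stability = stability, residual = residual,
                    stringsAsFactors = FALSE)
  class(out) <- c("fixed_points", class(out))
  out
}

#' Nullcline sections of the scalar Integrator equation
#'
#' Left- and right-hand side of the scalar fixed-point condition along a
#' grid of Integrator values, for graphical inspection of the solutions:
#' crossings of `lhs` (the identity) and `rhs` bracket the fixed points.
#'
#' @inheritParams solve_fixed_points
#' @param I_grid positive, strictly increasing Integrator values.
#' @return data frame with columns `I`, `lhs`, `rhs`.
#' @export
nullcline_sections <- function(p, z_value = p$beta_Z / p$v_Z,
                               dose = exogenous_dose(), I_grid) {
  if (any(I_grid <= 0) || is.unsorted(I_grid, strictly = TRUE))
    stop("I_grid must be positive and strictly increasing")
  data.frame(I = I_grid, lhs = I_grid,
             rhs = .fp_rhs(I_grid, p, z_value, dose))
}

#' Classify a parameter set into dynamical regimes
#'
#' Computes pre-rise (`z = 0`, no Z-coupled GA production) and post-rise
#' (`z = beta_Z / v_Z`) fixed points and derives the regime report used by
#' the parameter scans:
#' \itemize{
#'   \item `regime`: monostable / bistable / tristable from the number of
#'     stable post-rise fixed points;
#'   \item `flag_deterministic_non_germination`: the lowest stable
#'     post-rise Integrator state sits above the germination threshold, so
#'     no germination is expected in the deterministic limit;
#'   \item `flag_instantaneous_germination`: the highest stable pre-rise
#'     Integrator state is already below the threshold, i.e. seeds would
#'     germinate immediately on sowing (biologically irrelevant);
#'   \item `flag_germinates_without_rise`: seeds germinate even with the
#'     sowing-induced GA rise removed (`beta_GA_Z = 0`). The default
#'     strategy simulates `n_check` seeds stochastically from the initial
#'     state; the `"deterministic"` proxy instead flags when the lowest
#'     stable pre-rise state is below threshold. The proxy is conservative:
#'     at the reference defaults the pre-rise system has a low stable
#'     branch below threshold that seeds starting in the high-Integrator
#'     state essentially never reach within the simulation window, so the
#'     stochastic check (as used for the published exclusions) is the
#'     default.
#' }
#' A point is `biologically_relevant` when none of the three flags is set.
#'
#' @inheritParams solve_fixed_points
#' @param threshold germination threshold on the Integrator.
#' @param check_no_rise one of "stochastic", "deterministic", "none".
#' @param n_check number of seeds for the stochastic no-rise check.
#' @param settings [simulation_settings()] template for the stochastic
#'   check (its `n_seeds` is overridden by `n_check`).
#' @return An object of class `regime_report` (a list).
#' @export
classify_regime <- function(p, dose = exogenous_dose(), threshold = 1,
                            check_no_rise = c("stochastic", "deterministic", "none"),
                            n_check = 40, tol = 1e-10,
                            settings = NULL) {
  stopifnot(threshold > 0)
  check_no_rise <- match.arg(check_no_rise)
  pre  <- solve_fixed_points(p, z_value = 0, dose = dose, tol = tol)
  post <- solve_fixed_points(p, z_value = p$beta_Z / p$v_Z, dose = dose, tol = tol)
  if (!nrow(post))
    stop("no post-rise fixed point: the Integrator steady-state equation is degenerate")
  if (!nrow(pre))
    stop("no pre-rise fixed point: the Integrator steady-state equation is degenerate")

  post_stable <- post$I[post$stability == "stable"]
  pre_stable  <- pre$I[pre$stability == "stable"]
  n_stable <- length(post_stable)
  regime <- c("monostable", "bistable", "tristable")[min(n_stable, 3)]

  flag_det_non_germ <- min(post_stable) > threshold
  flag_instant <- max(pre_stable) < threshold

  flag_no_rise <- switch(check_no_rise,
    none = FALSE,
    deterministic = min(pre_stable) < threshold,
    stochastic = {
      p0 <- update_parameters(p, beta_GA_Z = 0)
      s <- if (is.null(settings)) simulation_settings(n_seeds = n_check,
                                                      germination_threshold = threshold)
           else simulation_settings(base = settings, n_seeds = n_check,
                                    germination_threshold = threshold)
      res <- simulate_ensemble(p0, dose = dose, settings = s,
                               init = initial_state(p))
      length(res$germination_times) > 0
    })

  structure(list(
    n_stable_post_rise = n_stable,
    regime = regime,
    flag_instantaneous_germination = flag_instant,
    flag_deterministic_non_germination = flag_det_non_germ,
    flag_germinates_without_rise = flag_no_rise,
    biologically_relevant = !flag_instant && !flag_det_non_germ && !flag_no_rise,
    threshold = threshold,
    pre_rise = pre, post_rise = post,
    check_no_rise = check_no_rise
  ), class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("%s (%d stable post-rise fixed point%s)\n", x$regime,
              x$n_stable_post_rise, if (x$n_stable_post_rise == 1) "" else "s"))
  cat(sprintf("  instantaneous germination:       %s\n", x$flag_instantaneous_germination))
  cat(sprintf("  deterministic non-germination:   %s\n", x$flag_deterministic_non_germination))
  cat(sprintf("  germinates without GA rise:      %s (%s check)\n",
              x$flag_germinates_without_rise, x$check_no_rise))
  cat(sprintf("  biologically relevant:           %s\n", x$biologically_relevant))
  invisible(x)
}

#' One row of regime flags for tidy CSV export
#' @param report a `regime_report`.
#' @return single-row data frame with flags as 0/1.
#' @export
regime_as_row <- function(report) {
  stopifnot(inherits(report, "regime_report"))
  data.frame(
    n_stable_post_rise = report$n_stable_post_rise,
    regime = report$regime,
    flag_instantaneous_germination = as.integer(report$flag_instantaneous_germination),
    flag_deterministic_non_germination = as.integer(report$flag_deterministic_non_germination),
    flag_germinates_without_rise = as.integer(report$flag_germinates_without_rise),
    biologically_relevant = as.integer(report$biologically_relevant),
    stringsAsFactors = FALSE)
}
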