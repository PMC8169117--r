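#' Logarithmically spaced parameter grid
#'
#' Geometric sequence with `per_decade` values per order of magnitude
#' (ratio `10^(1/per_decade)`), clipped so that both bounds are included.
#'
#' @param lo,hi positive bounds, `lo <= hi`.
#' @param per_decade values per decade (scan protocol uses 4-5).
#' @return numeric vector from `lo` to `hi`.
#' @export
geometric_grid <- function(lo, hi, per_decade = 4) {
  if (!(lo > 0) || !(hi > 0)) stop("bounds must be strictly positive")
  if (hi < lo) stop("hi must be >= lo")
  if (hi == lo) return(lo)
  k <- floor(log10(hi / lo) * per_decade + 1e-9)
  g <- lo * 10^(seq_len(k) / per_decade)
  unique(c(lo, g[g < hi * (1 - 1e-12)], hi))
}

# Deterministic seed derivation: fold the master seed and a set of index /
# value tokens through Lehmer steps modulo 2^31 - 1. Stays below 2^31 and
# depends only on the token values, so scans are order-independent.
derive_seed <- function(master, ...) {
  m <- 2147483647
  a <- (as.numeric(master) %% m) + 1
  for (tok in list(...)) {
    chars <- utf8ToInt(paste(format(tok, digits = 15), collapse = "|"))
    for (ch in chars) a <- (a * 48271 + ch) %% m
    a <- (a * 16807) %% m
  }
  as.numeric(a %% 2147483629) + 1
}

#' 1D/2D parameter scan with regime classification
#'
#' For every point of a 1- or 2-axis parameter grid: classify the
#' dynamical regime, apply the biological-relevance exclusions
#' (germination without the GA rise, instantaneous germination,
#' deterministic non-germination), and - for all points - run
#' `n_replicates` independent stochastic ensembles and summarize the
#' germination-time traits. Excluded points retain their regime data but
#' are marked not biologically relevant; trait values are additionally
#' subject to the 1%-germination reporting filter of [summarize_times()].
#'
#' Per-point, per-replicate RNG seeds are derived deterministically from
#' the master seed and the point's parameter values, so permuting the grid
#' order leaves every per-point result unchanged.
#'
#' @param base an [model_parameters()] object.
#' @param axes named list of 1 or 2 numeric grids; names must be parameter
#'   fields (e.g. `list(theta_I_ABA = geometric_grid(3, 10, 5))`).
#' @param settings a [simulation_settings()]; `n_seeds` defaults used as-is
#'   (figure protocol: 4000 for 1D headline scans, 400 for 2D scans).
#' @param n_replicates independent ensembles per point (default 3).
#' @param dose an [exogenous_dose()] applied at every point.
#' @param check_no_rise strategy for the no-rise germination exclusion
#'   (see [classify_regime()]); the stochastic check uses `n_check` seeds.
#' @param n_check seeds for the stochastic no-rise check (default 40).
#' @param bin_width histogram bin width for the germination-time mode, in
#'   simulation time units. The default 20 is the package's time-to-day
#'   scale (one "day" of the emulated daily scoring; see [line_spec()]):
#'   estimating the mode of a few hundred continuous times on unit bins is
#'   degenerate, whereas day-resolution mirrors how the experimental mode
#'   is scored.
#' @return A tidy data frame, one row per point x replicate, with the
#'   parameter values, regime fields (0/1 flags), replicate number, seed
#'   and trait columns (`cv`, `mean`, `mode`, `pct_germination`,
#'   `reportable`). Trait columns are `NA` where the reporting filter
#'   withholds them.
#' @export
parameter_scan <- function(base, axes, settings = simulation_settings(n_seeds = 400),
                           n_replicates = 3, dose = exogenous_dose(),
                           check_no_rise = "stochastic", n_check = 40,
                           bin_width = 20) {
  if (!is.list(axes) || is.null(names(axes)) ||
      !(length(axes) %in% 1:2) || any(names(axes) == ""))
    stop("axes must be a named list of 1 or 2 grids")
  unknown <- setdiff(names(axes), names(unclass(base)))
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  threshold <- settings$germination_threshold

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    overrides <- as.list(grid[i, , drop = FALSE])
    p_i <- do.call(update_parameters, c(list(base), overrides))
    regime <- classify_regime(p_i, dose = dose, threshold = threshold,
                              check_no_rise = check_no_rise, n_check = n_check,
                              settings = settings)
    reg_row <- regime_as_row(regime)
    init <- initial_state(p_i)
    reps <- lapply(seq_len(n_replicates), function(r) {
      seed_r <- derive_seed(settings$rng_seed, unlist(overrides), r)
      s_r <- simulation_settings(base = settings, rng_seed = seed_r)
      ens <- simulate_ensemble(p_i, dose = dose, settings = s_r, init = init)
      ts <- summarize_times(ens$germination_times, n_sown = ens$n_seeds,
                            bin_width = bin_width)
      traits <- data.frame(cv = ts$cv, mean = ts$mean, mode = ts$mode,
                           pct_germination = ts$pct_germination,
                           reportable = ts$reportable)
      if (!ts$reportable)
        traits[c("cv", "mean", "mode")] <- NA_real_
      cbind(data.frame(point = i, overrides, replicate = r,
                       rng_seed = seed_r, stringsAsFactors = FALSE),
            reg_row, traits)
    })
    do.call(rbind, reps)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exogenous hormone dose-response experiment
#'
#' Simulates germination-time distributions for a "low-variability" and a
#' "high-variability" parameterization over a grid of exogenous ABA or GA
#' doses (the reference contrast differs only in the ABA threshold for
#' Integrator production: `theta_I_ABA = 7` vs `5.8`). Doses enter via the
#' Integrator equation only; all simulations start from the untreated
#' initial state. Validity checks mirror the published protocol: an error
#' is raised if a dose-0 control falls in the spontaneous (instantaneous)
#' germination region or germinates without the GA rise; non-control doses
#' have their region flags recorded but do not error.
#'
#' @param p_low,p_high parameter sets for the two line classes.
#' @param hormone `"ABA"` or `"GA"`.
#' @param dose_grid non-negative doses; must include 0 (vehicle control).
#' @param settings a [simulation_settings()] (protocol: 4000 seeds).
#' @param n_replicates independent ensembles per dose (protocol: 5).
#' @param n_check_control seeds for the control no-rise check
#'   (protocol: 4000; reduce for quick runs).
#' @param bin_width mode bin width in time units (see [parameter_scan()]).
#' @return tidy data frame: one row per line class x dose x replicate with
#'   trait columns and regime flags at that dose.
#' @export
dose_response <- function(p_low, p_high, hormone = c("ABA", "GA"), dose_grid,
                          settings = simulation_settings(n_seeds = 4000),
                          n_replicates = 5, n_check_control = 4000,
                          bin_width = 20) {
  hormone <- match.arg(hormone)
  if (any(dose_grid < 0)) stop("doses must be non-negative")
  if (!any(dose_grid == 0)) stop("dose_grid must include 0 (vehicle control)")
  classes <- list(low = p_low, high = p_high)
  threshold <- settings$germination_threshold

  rows <- list()
  for (cls in names(classes)) {
    p <- classes[[cls]]
    init <- initial_state(p)
    for (d in dose_grid) {
      dose <- if (hormone == "ABA") exogenous_dose(ABA = d) else exogenous_dose(GA = d)
      is_control <- d == 0
      regime <- classify_regime(p, dose = dose, threshold = threshold,
                                check_no_rise = if (is_control) "stochastic" else "none",
                                n_check = n_check_control, settings = settings)
      if (is_control) {
        if (regime$flag_instantaneous_germination)
          stop("control (", cls, " class) falls in the spontaneous germination region")
        if (regime$flag_germinates_without_rise)
          stop("control (", cls, " class) germinates without the rise in GA production")
        if (regime$flag_deterministic_non_germination)
          stop("control (", cls, " class) falls in the deterministic non-germination region")
      }
      for (r in seq_len(n_replicates)) {
        seed_r <- derive_seed(settings$rng_seed, cls, hormone, d, r)
        s_r <- simulation_settings(base = settings, rng_seed = seed_r)
        ens <- simulate_ensemble(p, dose = dose, settings = s_r, init = init)
        ts <- summarize_times(ens$germination_times, n_sown = ens$n_seeds,
                              bin_width = bin_width)
        traits <- data.frame(cv = ts$cv, mean = ts$mean, mode = ts$mode,
                             pct_germination = ts$pct_germination,
                             reportable = ts$reportable)
        if (!ts$reportable) traits[c("cv", "mean", "mode")] <- NA_real_
        rows[[length(rows) + 1]] <- cbind(
          data.frame(line_class = cls, hormone = hormone, dose = d,
                     replicate = r, rng_seed = seed_r, stringsAsFactors = FALSE),
          regime_as_row(regime), traits)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
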