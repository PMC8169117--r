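#' Specify a synthetic line
#'
#' A line is generated either parametrically, by drawing integer
#' germination days from a named distribution, or model-driven, by
#' simulating a stochastic ensemble and binning the germination times into
#' days. Parametric generators:
#' \describe{
#'   \item{`peaked`}{discretized normal: `round(rnorm(mu, sigma))`,
#'     clamped to day >= 1 (low-variability, unimodal lines).}
#'   \item{`long_tailed`}{shifted gamma: `ceiling(start + rgamma(shape,
#'     scale))` (high-variability, long-tailed lines).}
#'   \item{`bimodal`}{two-component mixture of peaked distributions with
#'     mixture weight `w2` on the late component (very high variability
#'     lines whose late fraction produces CV > 0.6).}
#' }
#' Each seed germinates with probability `p_germ`; non-germinating seeds
#' and draws beyond the maximum scoring day are censored (counted as sown,
#' not germinated).
#'
#' @param line_id character id.
#' @param generator `"peaked"`, `"long_tailed"`, `"bimodal"` or `"model"`.
#' @param mu,sigma peaked parameters (also used by `bimodal` component 1).
#' @param start,shape,scale long-tailed parameters.
#' @param mu2,sigma2,w2 bimodal late component and weight.
#' @param p_germ per-seed germination probability.
#' @param parameters,dose model-driven generator inputs
#'   ([model_parameters()], [exogenous_dose()]).
#' @param day_scale model-driven time-to-day scale: `day = ceiling(t / day_scale)`.
#'   The default 20 maps the deterministic monostable crossing (t ~ 50 at the
#'   low-ABA-sensitivity reference parameterization) to day 3.
#' @return A `line_spec` list.
#' @export
line_spec <- function(line_id, generator = c("peaked", "long_tailed", "bimodal", "model"),
                      mu = 3, sigma = 0.4,
                      start = 2, shape = 1.5, scale = 3,
                      mu2 = 25, sigma2 = 2, w2 = 0.15,
                      p_germ = 1,
                      parameters = NULL, dose = exogenous_dose(),
                      day_scale = 20) {
  generator <- match.arg(generator)
  if (p_germ < 0 || p_germ > 1) stop("p_germ must be in [0, 1]")
  if (generator == "model" && is.null(parameters))
    stop("model-driven lines need a `parameters` object")
  if (generator %in% c("peaked", "bimodal") && sigma <= 0)
    stop("sigma must be > 0")
  if (generator == "long_tailed" && (shape <= 0 || scale <= 0))
    stop("shape and scale must be > 0")
  if (generator == "bimodal" && (w2 < 0 || w2 > 1 || sigma2 <= 0))
    stop("invalid mixture parameters")
  structure(list(line_id = as.character(line_id), generator = generator,
                 mu = mu, sigma = sigma, start = start, shape = shape,
                 scale = scale, mu2 = mu2, sigma2 = sigma2, w2 = w2,
                 p_germ = p_germ, parameters = parameters, dose = dose,
                 day_scale = day_scale),
            class = "line_spec")
}

#' Synthetic experiment design
#'
#' A set of line specifications plus the experimental layout emulated by
#' the generator: `replicates` parent plants per line (default 3), one
#' plate of `seeds_per_plate` seeds (default 150) per parent plant, daily
#' scoring up to `max_day`.
#'
#' @param lines list of [line_spec()] objects.
#' @param replicates replicate parent plants per line.
#' @param seeds_per_plate seeds sown per plate.
#' @param max_day last scoring day; later germination is censored.
#' @param master_seed integer master RNG seed.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(lines, replicates = 3, seeds_per_plate = 150,
                             max_day = 40, master_seed = 1L) {
  if (!length(lines)) stop("need at least one line")
  if (!all(vapply(lines, inherits, logical(1), "line_spec")))
    stop("lines must be line_spec objects")
  if (replicates < 1 || seeds_per_plate < 1) stop("invalid design sizes")
  ids <- vapply(lines, `[[`, character(1), "line_id")
  if (anyDuplicated(ids)) stop("duplicate line ids")
  structure(list(lines = lines, replicates = as.integer(replicates),
                 seeds_per_plate = as.integer(seeds_per_plate),
                 max_day = as.integer(max_day),
                 master_seed = as.numeric(master_seed)),
            class = "synthetic_design")
}

# day pmf of a parametric line over 1..max_day plus censoring mass;
# exact enumeration, used for CV targets and goodness-of-fit tests
.line_day_pmf <- function(spec, max_day) {
  days <- seq_len(max_day)
  pm <- switch(spec$generator,
    peaked = {
      lo <- ifelse(days == 1, -Inf, days - 0.5)
      stats::pnorm(days + 0.5, spec$mu, spec$sigma) - stats::pnorm(lo, spec$mu, spec$sigma)
    },
    long_tailed = {
      # day d <=> start + gamma in (d-1, d]
      stats::pgamma(days - spec$start, spec$shape, scale = spec$scale) -
        stats::pgamma(days - 1 - spec$start, spec$shape, scale = spec$scale)
    },
    bimodal = {
      lo <- ifelse(days == 1, -Inf, days - 0.5)
      (1 - spec$w2) * (stats::pnorm(days + 0.5, spec$mu, spec$sigma) -
                         stats::pnorm(lo, spec$mu, spec$sigma)) +
        spec$w2 * (stats::pnorm(days + 0.5, spec$mu2, spec$sigma2) -
                     stats::pnorm(lo, spec$mu2, spec$sigma2))
    },
    stop("no closed-form day distribution for model-driven lines"))
  pm <- pm * spec$p_germ
  list(days = days, p = pm, p_censored = 1 - sum(pm))
}

#' Expected (target) CV of a parametric line
#'
#' Population CV of the integer-day distribution, computed by exact
#' enumeration of the day probability mass function (germinated seeds
#' only). Serves as the design's target for pipeline-recovery checks.
#'
#' @param spec a parametric [line_spec()].
#' @param max_day enumeration horizon.
#' @return list with `cv`, `mean`, `mode`.
#' @export
line_target_traits <- function(spec, max_day = 60) {
  pmf <- .line_day_pmf(spec, max_day)
  p <- pmf$p / sum(pmf$p)
  m <- sum(p * pmf$days)
  v <- sum(p * pmf$days^2) - m^2
  list(cv = sqrt(max(v, 0)) / m, mean = m, mode = pmf$days[which.max(p)])
}

# draw n germination days (NA = censored) for one plate
.draw_days <- function(spec, n, max_day) {
  germ <- stats::runif(n) < spec$p_germ
  days <- rep(NA_integer_, n)
  ng <- sum(germ)
  if (ng) {
    d <- switch(spec$generator,
      peaked = pmax(1L, as.integer(round(stats::rnorm(ng, spec$mu, spec$sigma)))),
      long_tailed = as.integer(ceiling(spec$start +
                                         stats::rgamma(ng, spec$shape, scale = spec$scale))),
      bimodal = {
        late <- stats::runif(ng) < spec$w2
        mu <- ifelse(late, spec$mu2, spec$mu)
        sg <- ifelse(late, spec$sigma2, spec$sigma)
        pmax(1L, as.integer(round(stats::rnorm(ng, mu, sg))))
      })
    d[d > max_day] <- NA_integer_
    days[germ] <- d
  }
  days
}

#' Generate a synthetic germination count dataset
#'
#' Draws per-seed germination days for every plate of the design and
#' returns a day-binned [germination_counts()] table (one row per plate
#' and day with at least one germination). Model-driven lines simulate a
#' stochastic ensemble of `seeds_per_plate` seeds and map times to days as
#' `ceiling(t / day_scale)`; days beyond `max_day` are censored. The
#' result is fully reproducible from the design's master seed; parametric
#' draws use R's RNG seeded per plate, model-driven plates use the
#' compiled generator's derived substreams.
#'
#' @param design a [synthetic_design()].
#' @return A [germination_counts()] data frame.
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  rows <- list()
  for (spec in design$lines) {
    init <- if (spec$generator == "model") initial_state(spec$parameters) else NULL
    for (r in seq_len(design$replicates)) {
      plate_id <- sprintf("%s_r%d", spec$line_id, r)
      seed_r <- derive_seed(design$master_seed, spec$line_id, r)
      if (spec$generator == "model") {
        s <- simulation_settings(n_seeds = design$seeds_per_plate,
                                 rng_seed = seed_r)
        ens <- simulate_ensemble(spec$parameters, dose = spec$dose,
                                 settings = s, init = init)
        days <- as.integer(ceiling(ens$times / spec$day_scale))
        days[!is.na(days) & days > design$max_day] <- NA_integer_
        days[!is.na(days) & days < 1L] <- 1L
      } else {
        set.seed(seed_r)
        days <- .draw_days(spec, design$seeds_per_plate, design$max_day)
      }
      tab <- table(days[!is.na(days)])
      if (length(tab)) {
        rows[[length(rows) + 1]] <- data.frame(
          line_id = spec$line_id, replicate_id = sprintf("r%d", r),
          plate_id = plate_id, day = as.integer(names(tab)),
          n_germinated = as.integer(tab), n_sown = design$seeds_per_plate,
          stringsAsFactors = FALSE)
      } else {
        # keep fully censored plates visible with a zero-count day-1 row
        rows[[length(rows) + 1]] <- data.frame(
          line_id = spec$line_id, replicate_id = sprintf("r%d", r),
          plate_id = plate_id, day = 1L, n_germinated = 0L,
          n_sown = design$seeds_per_plate, stringsAsFactors = FALSE)
      }
    }
  }
  germination_counts(do.call(rbind, rows))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Bundled reference design
#'
#' Fourteen synthetic lines spanning the phenotype classes observed across
#' MAGIC-style lines: peaked low-variability lines (CV targets ~0.1-0.2),
#' long-tailed high-variability lines, bimodal very-high-variability lines
#' (late fraction, CV > 0.6), one nearly non-germinating line that fails
#' the 10-germinated-seed plate filter, and two model-driven lines (the
#' monostable low-ABA-sensitivity and bistable high-ABA-sensitivity
#' parameterizations). Modes are arranged to increase with the CV targets,
#' emulating the observed weak positive CV-mode coupling.
#'
#' @param master_seed integer master seed.
#' @param include_model_lines logical; model-driven lines cost a stochastic
#'   ensemble each (drop them for very fast runs).
#' @return A [synthetic_design()].
#' @export
reference_design <- function(master_seed = 2021L, include_model_lines = TRUE) {
  lines <- list(
    line_spec("P01", "peaked", mu = 2, sigma = 0.2),
    line_spec("P02", "peaked", mu = 3, sigma = 0.35),
    line_spec("P03", "peaked", mu = 3, sigma = 0.45),
    line_spec("P04", "peaked", mu = 4, sigma = 0.8),
    line_spec("T01", "long_tailed", start = 2, shape = 2.0, scale = 1.0),
    line_spec("T02", "long_tailed", start = 2, shape = 1.5, scale = 2.0),
    line_spec("T03", "long_tailed", start = 3, shape = 1.2, scale = 3.0, p_germ = 0.9),
    line_spec("T04", "long_tailed", start = 3, shape = 1.0, scale = 5.0, p_germ = 0.8),
    line_spec("B01", "bimodal", mu = 4, sigma = 0.5, mu2 = 25, sigma2 = 2, w2 = 0.15),
    line_spec("B02", "bimodal", mu = 4, sigma = 0.6, mu2 = 30, sigma2 = 3, w2 = 0.25,
              p_germ = 0.9),
    line_spec("X01", "peaked", mu = 5, sigma = 1.5, p_germ = 0.03),
    line_spec("U01", "long_tailed", start = 1, shape = 0.8, scale = 8.0, p_germ = 0.7))
  if (include_model_lines) {
    lines <- c(lines, list(
      line_spec("MLOW", "model",
                parameters = model_parameters(theta_I_ABA = 7)),
      line_spec("MHIGH", "model",
                parameters = model_parameters(theta_I_ABA = 5.8))))
  }
  synthetic_design(lines, replicates = 3, seeds_per_plate = 150,
                   max_day = 40, master_seed = master_seed)
}

#' Read / write germination count tables as CSV
#'
#' Plain CSV with header
#' `line_id,replicate_id,plate_id,day,n_germinated,n_sown`.
#'
#' @param table a [germination_counts()] data frame.
#' @param path file path.
#' @return `read_counts` returns a validated [germination_counts()] table;
#'   `write_counts` returns `path` invisibly.
#' @export
write_counts <- function(table, path) {
  table <- germination_counts(as.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  germination_counts(utils::read.csv(path, stringsAsFactors = FALSE))
}
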