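#' Model parameters for the ABA-GA-Integrator germination switch
#'
#' Constructs the immutable parameter set of the hormone network model.
#' Defaults are the reference parameterization of the model (arbitrary
#' units). `beta_*` are basal production rates, `v_*` first-order
#' degradation rates, `theta_*` regulatory thresholds (the concentration at
#' which a regulatory function is half-maximal; the inverse of a threshold
#' can be read as a sensitivity), `C_*` the maximal coefficients of the
#' regulatory functions, `h` the shared Hill exponent and `V` the effective
#' system volume (noise intensity is `1/V`; the deterministic limit is
#' recovered as `V -> Inf`).
#'
#' `beta_GA_Z` is a first-order coefficient coupling the sowing factor Z
#' into GA production; it is the only parameter allowed to be zero (setting
#' it to 0 removes the sowing-induced rise in GA production and is used by
#' the pre-sowing exclusion checks).
#'
#' @param ... named parameter overrides; unknown names are an error.
#' @param base parameter object to start from (default: package defaults).
#' @return An object of class `aba_ga_parameters` (a named list).
#' @examples
#' p <- model_parameters()                  # defaults
#' p_hi <- model_parameters(theta_I_ABA = 5.8)  # high ABA-sensitivity line
#' @export
model_parameters <- function(..., base = NULL) {
  p <- if (is.null(base)) .default_parameters else unclass(base)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    for (nm in names(dots)) p[[nm]] <- as.numeric(dots[[nm]])
  }
  validate_parameters(p)
  structure(p, class = "aba_ga_parameters")
}

# Reference defaults of the germination switch model (arbitrary units).
.default_parameters <- list(
  beta_ABA   = 1,
  beta_GA    = 0.3,
  beta_GA_Z  = 0.01,
  beta_Z     = 39,
  beta_I     = 0.3,
  v_ABA      = 1,
  v_GA       = 1,
  v_Z        = 0.1,
  v_I        = 0.4,
  theta_ABA_I = 3.7,
  theta_GA_I  = 1.2,
  theta_I_ABA = 6.5,
  theta_I_GA  = 6,
  C_ABA_I    = 10,
  C_GA_I     = 4,
  C_I_ABA    = 10,
  C_I_GA     = 6,
  h          = 4,
  V          = 30
)

#' @rdname model_parameters
#' @export
default_parameters <- function() model_parameters()

validate_parameters <- function(p) {
  nm <- names(.default_parameters)
  missing <- setdiff(nm, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  vals <- unlist(p[nm])
  if (!all(is.finite(vals)))
    stop("all parameters must be finite")
  # beta_GA_Z may be zero (no sowing-induced GA rise); everything else > 0
  strict <- setdiff(nm, "beta_GA_Z")
  bad <- strict[unlist(p[strict]) <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  if (p$beta_GA_Z < 0) stop("beta_GA_Z must be >= 0")
  invisible(p)
}

#' Copy a parameter set with modified values
#'
#' Scans and sweeps never mutate a parameter object; they work on modified
#' copies produced here.
#'
#' @param p an `aba_ga_parameters` object.
#' @param ... named overrides.
#' @return A new `aba_ga_parameters` object.
#' @export
update_parameters <- function(p, ...) {
  stopifnot(inherits(p, "aba_ga_parameters"))
  model_parameters(..., base = p)
}

#' @export
print.aba_ga_parameters <- function(x, ...) {
  cat("ABA-GA germination switch parameters\n")
  v <- unlist(unclass(x))
  defaults <- unlist(.default_parameters)
  mark <- ifelse(v != defaults[names(v)], " *", "")
  cat(sprintf("  %-12s %g%s\n", names(v), v, mark), sep = "")
  if (any(mark != "")) cat("  (* differs from default)\n")
  invisible(x)
}

#' Exogenous hormone dose
#'
#' Constant exogenous ABA and GA concentrations. Doses enter the model only
#' through the Integrator equation (added to the endogenous hormone
#' concentration inside its regulatory functions), never through the
#' endogenous ABA/GA production equations.
#'
#' @param ABA,GA non-negative constant concentrations.
#' @return An object of class `exogenous_dose`.
#' @export
exogenous_dose <- function(ABA = 0, GA = 0) {
  ABA <- as.numeric(ABA); GA <- as.numeric(GA)
  if (length(ABA) != 1 || length(GA) != 1 || !is.finite(ABA) || !is.finite(GA) ||
      ABA < 0 || GA < 0)
    stop("exogenous doses must be single finite non-negative numbers")
  structure(list(ABA = ABA, GA = GA), class = "exogenous_dose")
}

#' System state
#'
#' Concentrations of the four model variables at a time point. All
#' concentrations must be non-negative (the stochastic integrator enforces
#' an absorptive barrier at zero).
#'
#' @param ABA,GA,I,Z non-negative concentrations.
#' @param t time (arbitrary units).
#' @return A named numeric vector of class `system_state` with a `t` attribute.
#' @export
system_state <- function(ABA, GA, I, Z, t = 0) {
  x <- c(ABA = as.numeric(ABA), GA = as.numeric(GA),
         I = as.numeric(I), Z = as.numeric(Z))
  if (!all(is.finite(x))) stop("state concentrations must be finite")
  if (any(x < 0)) stop("state concentrations must be non-negative")
  structure(x, t = as.numeric(t), class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("state at t = %g: ABA = %g, GA = %g, I = %g, Z = %g\n",
              attr(x, "t"), x[["ABA"]], x[["GA"]], x[["I"]], x[["Z"]]))
  invisible(x)
}
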