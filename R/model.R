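#' Hill regulatory functions
#'
#' The model's regulatory interactions are Hill functions of a single
#' concentration. `hill_increasing(y) = C * y^h / (theta^h + y^h)` is used
#' for activation (and for GA-promoted Integrator degradation, where it
#' scales a first-order rate); `hill_decreasing(y) = C / (1 + (y/theta)^h)`
#' for repression. The two are complementary:
#' `hill_increasing + hill_decreasing = C` for equal arguments.
#'
#' @param y concentration(s), non-negative.
#' @param C maximal coefficient, > 0.
#' @param theta half-maximal threshold, > 0.
#' @param h Hill exponent, > 0.
#' @return Rate value(s) in `[0, C)` (increasing) or `(0, C]` (decreasing).
#' @export
hill_increasing <- function(y, C, theta, h) {
  .check_hill_args(y, C, theta, h)
  r <- (y / theta)^h
  C * r / (1 + r)
}

#' @rdname hill_increasing
#' @export
hill_decreasing <- function(y, C, theta, h) {
  .check_hill_args(y, C, theta, h)
  C / (1 + (y / theta)^h)
}

.check_hill_args <- function(y, C, theta, h) {
  if (any(!is.finite(y)) || any(y < 0))
    stop("hill function input must be finite and non-negative")
  if (any(C <= 0) || any(theta <= 0) || any(h <= 0))
    stop("C, theta and h must be strictly positive")
}

.as_state <- function(state) {
  if (inherits(state, "system_state")) return(unclass(state))
  x <- as.numeric(state[c("ABA", "GA", "I", "Z")])
  if (any(is.na(x))) stop("state must have components ABA, GA, I, Z")
  names(x) <- c("ABA", "GA", "I", "Z")
  x
}

#' Deterministic drift of the germination switch
#'
#' Right-hand sides of the four rate equations:
#' \deqn{d[ABA]/dt = \beta_{ABA} + f_{ABA}([I]) - v_{ABA}[ABA]}
#' \deqn{d[GA]/dt  = \beta_{GA} + \beta_{GA,Z}[Z] + g_{GA}([I]) - v_{GA}[GA]}
#' \deqn{d[I]/dt   = \beta_I + f_I([ABA]+[ABA]_{exo})
#'                   - (v_I + f_{I,GA}([GA]+[GA]_{exo}))[I]}
#' \deqn{d[Z]/dt   = \beta_Z - v_Z[Z]}
#' where `f` are increasing and `g` decreasing Hill functions. Exogenous
#' hormone doses enter only the Integrator equation.
#'
#' @param state a [system_state()] (or named vector with ABA, GA, I, Z).
#' @param p an [model_parameters()] object.
#' @param dose an [exogenous_dose()].
#' @return Named numeric vector of rates over (ABA, GA, I, Z).
#' @export
drift <- function(state, p, dose = exogenous_dose()) {
  x <- .as_state(state)
  if (any(x < 0)) stop("negative concentration in state")
  f_ABA  <- hill_increasing(x[["I"]], p$C_ABA_I, p$theta_ABA_I, p$h)
  g_GA   <- hill_decreasing(x[["I"]], p$C_GA_I, p$theta_GA_I, p$h)
  f_I    <- hill_increasing(x[["ABA"]] + dose$ABA, p$C_I_ABA, p$theta_I_ABA, p$h)
  f_I_GA <- hill_increasing(x[["GA"]] + dose$GA, p$C_I_GA, p$theta_I_GA, p$h)
  c(ABA = p$beta_ABA + f_ABA - p$v_ABA * x[["ABA"]],
    GA  = p$beta_GA + p$beta_GA_Z * x[["Z"]] + g_GA - p$v_GA * x[["GA"]],
    I   = p$beta_I + f_I - (p$v_I + f_I_GA) * x[["I"]],
    Z   = p$beta_Z - p$v_Z * x[["Z"]])
}

#' Langevin diffusion amplitudes
#'
#' Multipliers of the unit-intensity Gaussian white noises in the chemical
#' Langevin equations. For each variable the squared amplitude is the sum
#' of the magnitudes of its production and degradation terms divided by
#' `2V`, so amplitudes scale as `V^(-1/2)` and vanish in the deterministic
#' limit `V -> Inf`. The prefactor convention is isolated in
#' `.langevin_prefactor` so the alternative `1/V` reading is a one-line
#' change.
#'
#' @inheritParams drift
#' @return Named non-negative numeric vector of amplitudes over
#'   (ABA, GA, I, Z).
#' @export
diffusion_amplitude <- function(state, p, dose = exogenous_dose()) {
  x <- .as_state(state)
  if (any(x < 0)) stop("negative concentration in state")
  if (!is.finite(p$V) || p$V <= 0) stop("V must be strictly positive")
  f_ABA  <- hill_increasing(x[["I"]], p$C_ABA_I, p$theta_ABA_I, p$h)
  g_GA   <- hill_decreasing(x[["I"]], p$C_GA_I, p$theta_GA_I, p$h)
  f_I    <- hill_increasing(x[["ABA"]] + dose$ABA, p$C_I_ABA, p$theta_I_ABA, p$h)
  f_I_GA <- hill_increasing(x[["GA"]] + dose$GA, p$C_I_GA, p$theta_I_GA, p$h)
  sums <- c(ABA = p$beta_ABA + f_ABA + p$v_ABA * x[["ABA"]],
            GA  = p$beta_GA + p$beta_GA_Z * x[["Z"]] + g_GA + p$v_GA * x[["GA"]],
            I   = p$beta_I + f_I + (p$v_I + f_I_GA) * x[["I"]],
            Z   = p$beta_Z + p$v_Z * x[["Z"]])
  sqrt(.langevin_prefactor(p$V) * sums)
}

# amplitude^2 = (production + degradation) / (2V)
.langevin_prefactor <- function(V) 1 / (2 * V)
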