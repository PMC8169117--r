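# shared fixtures: reference parameterizations and small settings

p_default <- model_parameters()
p_mono <- model_parameters(theta_I_ABA = 7)     # low-variability class
p_bist <- model_parameters(theta_I_ABA = 5.8)   # high-variability class

# linear decoupled model: all regulatory coefficients effectively off
# (C must stay > 0; 1e-12 is numerically off)
p_linear <- model_parameters(C_ABA_I = 1e-12, C_GA_I = 1e-12,
                             C_I_ABA = 1e-12, C_I_GA = 1e-12)

quick_settings <- function(n_seeds = 100, rng_seed = 1, ...) {
  simulation_settings(n_seeds = n_seeds, rng_seed = rng_seed, ...)
}

z_post <- function(p) p$beta_Z / p$v_Z

# random parameter draw within a multiplicative factor of the defaults
draw_parameters <- function(fac = 3, include_h = TRUE) {
  nm <- c("beta_ABA", "beta_GA", "beta_GA_Z", "beta_Z", "beta_I",
          "v_ABA", "v_GA", "v_Z", "v_I",
          "theta_ABA_I", "theta_GA_I", "theta_I_ABA", "theta_I_GA",
          "C_ABA_I", "C_GA_I", "C_I_ABA", "C_I_GA",
          if (include_h) "h")
  f <- exp(stats::runif(length(nm), log(1 / fac), log(fac)))
  ov <- as.list(unlist(unclass(model_parameters()))[nm] * f)
  do.call(model_parameters, ov)
}
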