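test_that("hill functions match their closed forms", {
  # half-maximal at threshold, zero/limit behaviour
  expect_equal(hill_increasing(6.5, 10, 6.5, 4), 5)
  expect_equal(hill_increasing(0, 10, 6.5, 4), 0)
  expect_equal(hill_increasing(13, 10, 6.5, 4), 10 * 16 / 17)  # y = 2*theta
  expect_equal(hill_decreasing(0, 4, 1.2, 4), 4)
  expect_equal(hill_decreasing(1.2, 4, 1.2, 4), 2)
  expect_lt(hill_decreasing(1e9, 4, 1.2, 4), 1e-12)

  expect_error(hill_increasing(-1, 10, 6.5, 4), "non-negative")
  expect_error(hill_increasing(NaN, 10, 6.5, 4), "finite")
  expect_error(hill_decreasing(1, -1, 6.5, 4), "strictly positive")
})

test_that("increasing and decreasing hill functions are complementary", {
  set.seed(1)
  for (i in 1:50) {
    y <- stats::rexp(1, 1 / 5); C <- stats::rexp(1); th <- stats::rexp(1, 1 / 3)
    h <- stats::runif(1, 0.5, 8)
    expect_equal(hill_increasing(y, C, th, h) + hill_decreasing(y, C, th, h), C)
  }
  # monotonicity on a grid
  y <- seq(0, 50, by = 0.25)
  expect_true(all(diff(hill_increasing(y, 10, 6.5, 4)) > 0))
  expect_true(all(diff(hill_decreasing(y, 4, 1.2, 4)) < 0))
})

test_that("parameter constructor validates and defaults correctly", {
  p <- model_parameters()
  expect_equal(p$theta_I_ABA, 6.5)
  expect_equal(p$V, 30)
  expect_equal(p$beta_Z, 39)
  p2 <- update_parameters(p, theta_I_ABA = 5.8)
  expect_equal(p2$theta_I_ABA, 5.8)
  expect_equal(p$theta_I_ABA, 6.5)  # copies, never mutation
  expect_error(model_parameters(theta_IABA = 5.8), "unknown parameter")
  expect_error(model_parameters(v_ABA = -1), "strictly positive")
  expect_error(model_parameters(beta_GA_Z = -0.1), ">= 0")
  expect_silent(model_parameters(beta_GA_Z = 0))
})

test_that("drift reproduces the rate equations", {
  # linear decoupled model: unique fixed point at beta/v component-wise
  st <- system_state(1, 4.2, 0.75, 390)
  expect_equal(unname(drift(st, p_linear)), rep(0, 4), tolerance = 1e-9)

  # all-zero state: regulatory functions at zero arguments
  st0 <- system_state(0, 0, 0, 0)
  expect_equal(drift(st0, p_default),
               c(ABA = 1, GA = 0.3 + 4, I = 0.3, Z = 39))

  # saturation: Integrator production bounded by beta_I + C_I_ABA
  st1 <- system_state(2, 3, 1.5, 100)
  d_inf <- drift(st1, p_default, exogenous_dose(ABA = 1e12))
  f_I_GA <- hill_increasing(3, p_default$C_I_GA, p_default$theta_I_GA, p_default$h)
  expect_equal(d_inf[["I"]],
               p_default$beta_I + p_default$C_I_ABA -
                 (p_default$v_I + f_I_GA) * 1.5,
               tolerance = 1e-9)

  expect_error(drift(c(ABA = -1, GA = 0, I = 0, Z = 0), p_default), "negative")
})

test_that("exogenous doses enter only the Integrator equation", {
  st <- system_state(1.3, 2.1, 4, 100)
  d0 <- drift(st, p_default)
  d1 <- drift(st, p_default, exogenous_dose(ABA = 2, GA = 1.5))
  expect_equal(d1[c("ABA", "GA", "Z")], d0[c("ABA", "GA", "Z")])
  expect_false(isTRUE(all.equal(d1[["I"]], d0[["I"]])))
})

test_that("diffusion amplitudes follow the chemical-Langevin convention", {
  st0 <- system_state(0, 0, 0, 0)
  a <- diffusion_amplitude(st0, p_default)
  expect_equal(a[["Z"]], sqrt(39 / 60))  # only production term at zero state

  # deterministic limit
  p_big <- update_parameters(p_default, V = 1e12)
  st <- system_state(5, 5, 5, 400)
  expect_true(all(diffusion_amplitude(st, p_big) < 1e-4))

  # sqrt(2) scaling when every reaction term doubles
  p2 <- do.call(model_parameters, as.list(
    unlist(unclass(p_default))[c("beta_ABA", "beta_GA", "beta_GA_Z", "beta_Z",
                                 "beta_I", "v_ABA", "v_GA", "v_Z", "v_I",
                                 "C_ABA_I", "C_GA_I", "C_I_ABA", "C_I_GA")] * 2))
  expect_equal(unname(diffusion_amplitude(st, p2)),
               unname(sqrt(2) * diffusion_amplitude(st, p_default)),
               tolerance = 1e-12)
})

test_that("amplitude^2 * 2V equals the summed reaction magnitudes", {
  # independent reconstruction of the per-variable production/degradation sums
  set.seed(7)
  for (i in 1:20) {
    p <- draw_parameters()
    x <- stats::rexp(4, 1 / 5)
    st <- system_state(x[1], x[2], x[3], x[4])
    dose <- exogenous_dose(ABA = stats::rexp(1), GA = stats::rexp(1))
    f_ABA <- hill_increasing(x[3], p$C_ABA_I, p$theta_ABA_I, p$h)
    g_GA  <- hill_decreasing(x[3], p$C_GA_I, p$theta_GA_I, p$h)
    f_I   <- hill_increasing(x[1] + dose$ABA, p$C_I_ABA, p$theta_I_ABA, p$h)
    f_IGA <- hill_increasing(x[2] + dose$GA, p$C_I_GA, p$theta_I_GA, p$h)
    sums <- c(p$beta_ABA + f_ABA + p$v_ABA * x[1],
              p$beta_GA + p$beta_GA_Z * x[4] + g_GA + p$v_GA * x[2],
              p$beta_I + f_I + (p$v_I + f_IGA) * x[3],
              p$beta_Z + p$v_Z * x[4])
    a <- diffusion_amplitude(st, p, dose)
    expect_equal(unname(a^2 * 2 * p$V), sums, tolerance = 1e-12)
  }
})

test_that("V must be positive for diffusion amplitudes", {
  st <- system_state(1, 1, 1, 1)
  p_bad <- unclass(p_default); p_bad$V <- -1
  expect_error(diffusion_amplitude(st, p_bad), "V must be")
})
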