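test_that("lumped parameters follow the energy balance", {
  # contrived single-material stack with areal heat capacity 1.39 J/(m^2 K)
  m <- bmc_material("m", 1390, 1000, 10)
  geom <- beam_geometry(600e-6, 76e-6, layer_stack(m, m, 0.5e-6, 0.5e-6))
  mod <- beam_model(geom, environment_spec(h_conv = 20,
                                           convection_sides = "one"),
                    irradiation(absorbed_flux = 500))
  p <- lumped_params(mod)
  expect_equal(p$c_areal, 1.39)
  expect_equal(p$tc, 1.39 / 20)           # 69.5 ms
  expect_equal(p$t_inf - p$t0, 25)        # q_s / h = 500 / 20
  # no flux: steady state is ambient
  p0 <- lumped_params(beam_model(geom, environment_spec(
    h_conv = 20, convection_sides = "one"), irradiation(absorbed_flux = 0)))
  expect_equal(p0$t_inf, p0$t0)
  # h = 0: no steady state, analytic path refuses
  ph <- lumped_params(beam_model(geom, environment_spec(h_conv = 0)))
  expect_true(ph$no_steady_state)
  expect_identical(ph$tc, Inf)
  expect_error(lumped_temperature(ph, 0.1), "no steady state")
})

test_that("analytic lumped solution has the right endpoints and e-folding", {
  p <- lumped_params(test_model())
  expect_equal(lumped_temperature(p, 0), p$t0)
  expect_equal(lumped_temperature(p, 100 * p$tc), p$t_inf)
  expect_equal(lumped_temperature(p, p$tc),
               p$t0 + (1 - exp(-1)) * (p$t_inf - p$t0))
  expect_error(lumped_temperature(p, -1), ">= 0")
})

test_that("numerical lumped integration matches the analytic solution", {
  mod <- test_model()
  p <- lumped_params(mod)
  times <- seq(0, 0.5, length.out = 401)
  an <- lumped_temperature(p, times)
  rise <- p$t_inf - p$t0
  ode <- simulate_lumped_ode(mod, times, method = "lsoda")
  expect_lt(max(abs(ode$temperature - an)) / rise, 1e-9)
  exact <- simulate_lumped_ode(mod, times, method = "exponential")
  expect_lt(max(abs(exact$temperature - an)) / rise, 1e-12)
  # no flux from ambient start: identically constant
  quiet <- simulate_lumped_ode(test_model(flux = 0), times)
  expect_equal(max(abs(quiet$temperature - quiet$temperature[1])), 0)
})

test_that("switching the flux off decays with the same time constant", {
  mod <- test_model(duration = 0.2)
  p <- lumped_params(mod)
  times <- seq(0, 0.8, length.out = 1601)
  trace <- simulate_lumped_ode(mod, times, method = "lsoda")
  decay <- times >= 0.2
  # map the decay branch through the mechanics and refit its time constant
  dt <- deflection_trace(thermal_trace(times[decay] - 0.2,
                                       trace$temperature[decay],
                                       t_ambient = p$t0),
                         mod)
  fit <- fit_exponential(dt)
  expect_true(fit$converged)
  expect_equal(fit$tau, p$tc, tolerance = 1e-6)
})

test_that("the lumped model conserves energy", {
  mod <- test_model()
  p <- lumped_params(mod)
  times <- seq(0, 0.4, length.out = 4001)
  temp <- simulate_lumped_ode(mod, times, method = "exponential")$temperature
  stored <- p$c_areal * (temp - p$t0)
  lost <- p$h_eff * pracma::cumtrapz(times, temp - p$t0)[, 1]
  supplied <- mod$irradiation$absorbed_flux * times
  expect_lt(max(abs(stored + lost - supplied)) /
              (mod$irradiation$absorbed_flux * 0.4), 1e-6)
})

test_that("heating from ambient is monotone and bounded by the steady state", {
  mod <- test_model()
  p <- lumped_params(mod)
  temp <- simulate_lumped_ode(mod, seq(0, 1, length.out = 500))$temperature
  expect_true(all(diff(temp) >= 0))
  expect_true(all(temp <= p$t_inf + 1e-12))
})

test_that("distributed model reproduces the lumped solution under uniform load", {
  mod <- test_model()
  p <- lumped_params(mod)
  times <- seq(0, 0.5, length.out = 251)
  an <- lumped_temperature(p, times)
  dist <- simulate_distributed_1d(mod, times, n_nodes = 31, substeps = 20)
  err <- max(abs(dist$temperature - an)) / (p$t_inf - p$t0)
  expect_lt(err, 1e-6)
  # unheated: identically ambient
  cold <- simulate_distributed_1d(test_model(flux = 0), times, n_nodes = 11)
  expect_equal(max(abs(cold$temperature - p$t0)), 0)
})

test_that("spatial uniformity metric behaves as a lumped-validity certificate", {
  mod <- test_model()
  times <- seq(0, 0.5, length.out = 101)
  uni <- simulate_distributed_1d(mod, times, n_nodes = 21)
  expect_lt(spatial_uniformity(uni), 1e-10)
  # a clamped-anchor beam develops gradients that sharpen as conductance
  # falls: the steady spatial spread, on the scale of the lumped rise q/h,
  # grows monotonically toward 1
  p <- lumped_params(mod)
  spread <- vapply(c(1, 1e-2, 1e-4), function(ks) {
    tr <- simulate_distributed_1d(mod, times, n_nodes = 41, anchor = "fixed",
                                  conductance_scale = ks)
    last <- tr$temperature[length(times), ]
    (max(last) - min(last)) / (p$t_inf - p$t0)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
  expect_true(all(spread <= 1 + 1e-9))
  lump <- simulate_lumped_ode(mod, times)
  expect_error(spatial_uniformity(lump), "distributed")
})

test_that("distributed solution converges under grid refinement", {
  mod <- test_model()
  times <- seq(0, 0.3, length.out = 61)
  tip_temp <- function(n, s)
    simulate_distributed_1d(mod, times, n_nodes = n, anchor = "fixed",
                            substeps = s)$temperature[61, n]
  coarse <- tip_temp(21, 2)
  mid <- tip_temp(41, 4)
  fine <- tip_temp(81, 8)
  expect_lt(abs(fine - mid), abs(mid - coarse))
})
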