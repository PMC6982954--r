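test_that("curvature coefficient K has the symmetric-stack value", {
  expect_equal(curvature_coefficient_K(ratio_stack(1, 1, 1e-5)), 16)
  # default stack: m = 2, n = 25/7
  expect_equal(curvature_coefficient_K(test_stack()),
               4 + 12 + 16 + (25 / 7) * 8 + 7 / 50)
  m <- default_materials()$si3n4
  expect_error(layer_stack(m, m, 1e-6, 0), "t_bottom")
})

test_that("thermal curvature vanishes without mismatch or temperature change", {
  expect_equal(curvature_from_dT(test_stack(), 0), 0)
  expect_equal(curvature_from_dT(ratio_stack(1.7, 2.3, 0), 25), 0)
})

test_that("symmetric-stack curvature reduces to the closed form", {
  # equal layers: kappa = 0.75 * dAlpha * dT / t  (t the layer thickness)
  st <- ratio_stack(1, 1, 20e-6)
  expect_equal(curvature_from_dT(st, 10), 0.75 * 20e-6 * 10 / 1e-6)  # 150 1/m
  # textbook limit: kappa = (3/2) dAlpha dT / t_total
  expect_equal(timoshenko_curvature(st, 10), 1.5 * 20e-6 * 10 / 2e-6,
               tolerance = 1e-12)
})

test_that("two-layer curvature equals the classical bimetal-strip oracle", {
  set.seed(202)
  for (i in 1:1000) {
    st <- ratio_stack(m = 10^runif(1, -1.5, 1.5), n = 10^runif(1, -1.5, 1.5),
                      d_alpha = runif(1, -5e-5, 5e-5),
                      t_bottom = 10^runif(1, -7, -5))
    dT <- runif(1, -50, 50)
    a <- curvature_from_dT(st, dT)
    b <- timoshenko_curvature(st, dT)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("deflection integration matches closed forms", {
  x <- seq(0, 600e-6, length.out = 301)
  # uniform curvature: z = kappa x^2 / 2 exactly (trapezoid is exact here)
  prof <- integrate_deflection(x, rep(150, 301))
  expect_equal(prof$tip_deflection, 150 * (600e-6)^2 / 2)
  expect_equal(prof$z, 150 * x^2 / 2)
  # zero curvature: identically zero
  expect_equal(integrate_deflection(x, rep(0, 301))$z, rep(0, 301))
  # linear curvature c*x: tip = c L^3 / 6, second-order convergence
  c0 <- 2e5
  err_at <- function(n) {
    xg <- seq(0, 600e-6, length.out = n)
    abs(integrate_deflection(xg, c0 * xg)$tip_deflection -
          c0 * (600e-6)^3 / 6)
  }
  e1 <- err_at(51); e2 <- err_at(101)
  expect_lt(e2, e1)
  expect_equal(e1 / e2, 4, tolerance = 0.1)
  expect_error(integrate_deflection(rev(x), rep(1, 301)), "increasing")
})

test_that("clamped-anchor conditions hold at the wall", {
  x <- seq(0, 600e-6, length.out = 201)
  prof <- integrate_deflection(x, 100 + 5e4 * x)
  expect_equal(prof$z[1], 0)
  # discrete slope at the anchor vanishes to first order
  expect_lt(abs(prof$z[2] - prof$z[1]) / abs(prof$tip_deflection), 1e-4)
})

test_that("tip deflection is an exact linear map of temperature rise", {
  mod <- test_model()
  times <- seq(0, 0.5, length.out = 200)
  th <- simulate_lumped_ode(mod, times, method = "exponential")
  tr <- deflection_trace(th, mod)
  rise <- th$temperature - th$temperature[1]
  expect_equal(cor(rise[-1], tr$tip[-1]), 1)
  # doubling the temperature rise doubles the deflection
  th2 <- thermal_trace(times, th$temperature[1] + 2 * rise,
                       t_ambient = th$t_ambient)
  expect_equal(deflection_trace(th2, mod)$tip, 2 * tr$tip)
  # zero rise: zero trace
  th0 <- thermal_trace(times, rep(th$t_ambient, 200),
                       t_ambient = th$t_ambient)
  expect_equal(deflection_trace(th0, mod)$tip, rep(0, 200))
})

test_that("heating deflects toward the structural layer when the coating expands more", {
  mod <- test_model()   # aluminium (larger alpha) on the bottom
  times <- seq(0, 0.5, length.out = 100)
  tr <- deflection_trace(simulate_lumped_ode(mod, times), mod)
  expect_true(all(tr$tip[-1] > 0))
})

test_that("distributed and lumped mechanics agree for a uniform field", {
  mod <- test_model()
  times <- seq(0, 0.3, length.out = 61)
  lump <- deflection_trace(simulate_lumped_ode(mod, times), mod)
  dist <- deflection_trace(
    simulate_distributed_1d(mod, times, n_nodes = 101, substeps = 10), mod)
  expect_equal(dist$tip, lump$tip, tolerance = 1e-5)
})

test_that("steady tip deflection is on the order of the published value", {
  mod <- test_model()
  p <- lumped_params(mod)
  tip <- curvature_from_dT(mod$geometry$stack, p$t_inf - p$t0) *
    mod$geometry$length^2 / 2
  # published: 178 um; material constants are not published, so this is an
  # order-of-magnitude anchor only
  expect_gt(tip, 178e-6 / 10)
  expect_lt(tip, 178e-6 * 10)
})
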