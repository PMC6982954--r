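test_that("mixture rule is a volume-weighted mean", {
  expect_equal(mixture_rho_cp(3e6, 3e6, 1e-13, 7e-15), 3e6)
  expect_equal(mixture_rho_cp(1.9e6, 5.4e6, 34, 1), 2.0e6)
  # vanishing sample volume: beam value
  expect_equal(mixture_rho_cp(1.9e6, 5.4e6, 1e-13, 1e-25), 1.9e6,
               tolerance = 1e-10)
})

test_that("mixture inversion is the exact algebraic inverse", {
  set.seed(404)
  for (i in 1:50) {
    rc_B <- 10^runif(1, 5, 7); rc_S <- 10^runif(1, 5, 7)
    v_B <- 10^runif(1, -14, -12); v_S <- v_B / runif(1, 2, 100)
    rc_T <- mixture_rho_cp(rc_B, rc_S, v_B, v_S)
    back <- suppressWarnings(invert_mixture(rc_T, rc_B, v_B, v_S))
    expect_equal(as.numeric(back), rc_S, tolerance = 1e-12)
  }
  expect_equal(as.numeric(suppressWarnings(invert_mixture(2.0e6, 1.9e6, 34, 1))),
               5.4e6, tolerance = 1e-12)
})

test_that("mixture inversion warns on cancellation and flags bad results", {
  # V_B/V_S large and nearly equal capacities: heavy cancellation
  expect_warning(invert_mixture(2.0e6, 2.0e6 * (1 - 1e-4), 100, 1),
                 "cancellation")
  # mixture below the beam-only bound: nonpositive, flagged invalid
  expect_warning(out <- invert_mixture(1.0e6, 1.9e6, 34, 1), "invalid")
  expect_false(attr(out, "valid"))
})

test_that("time constant and volumetric heat capacity are mutual inverses", {
  expect_equal(rho_cp_from_tau(0.230, 1.1e-6, 20), 0.230 * 20 / 1.1e-6)
  set.seed(505)
  for (i in 1:25) {
    rc <- 10^runif(1, 5, 7); lc <- 10^runif(1, -7, -5); h <- runif(1, 5, 50)
    expect_equal(rho_cp_from_tau(tau_from_rho_cp(rc, lc, h), lc, h), rc,
                 tolerance = 1e-12)
  }
  # tau is proportional to the characteristic length
  expect_equal(tau_from_rho_cp(2e6, 2e-6, 20), 2 * tau_from_rho_cp(2e6, 1e-6, 20))
  expect_error(tau_from_rho_cp(2e6, 1e-6, 0), "h_eff")
})

test_that("shortcut sample time constant reproduces the published evaluation", {
  # published fitted inputs: 66.5 / 69.3 ms, V_B/V_S = 34, Lc ratio 1.1/1.0;
  # the published text nevertheless states 230 ms (see reference_demo)
  tau_s <- sample_time_constant(66.5e-3, 69.3e-3, 1.0e-6, 1.1e-6, 34)
  expect_equal(as.numeric(tau_s), 1.1 * (69.3e-3 + 34 * (69.3e-3 - 66.5e-3)),
               tolerance = 1e-12)
  expect_equal(as.numeric(tau_s), 0.180950, tolerance = 1e-6)
  # zero increment: pure Lc rescaling of the calibration constant
  expect_equal(as.numeric(sample_time_constant(0.07, 0.07, 1e-6, 1.1e-6, 34)),
               1.1 * 0.07)
  # loaded faster than calibration by enough: invalid
  expect_warning(bad <- sample_time_constant(0.07, 0.0669, 1e-6, 1.1e-6, 34),
                 "invalid")
  expect_false(attr(bad, "valid"))
})

test_that("the mixture chain and the shortcut formula are algebraically identical", {
  set.seed(606)
  for (i in 1:50) {
    tau_B <- runif(1, 0.02, 0.2)
    tau_T <- tau_B * runif(1, 1.001, 1.5)
    lc_B <- 10^runif(1, -6.5, -5.5); lc_S <- lc_B * runif(1, 0.5, 2)
    lc_T <- lc_B * runif(1, 0.9, 1.1)
    R <- runif(1, 2, 100); h <- runif(1, 10, 50)
    v_S <- 10^runif(1, -16, -14); v_B <- R * v_S
    # route 1: generalised shortcut then tau -> rhoCp
    tau_s <- suppressWarnings(
      sample_time_constant(tau_B, tau_T, lc_B, lc_S, R, lc_T = lc_T))
    r1 <- as.numeric(tau_s) * h / lc_S
    # route 2: per-object rhoCp then mixture inversion
    r2 <- suppressWarnings(as.numeric(invert_mixture(
      rho_cp_from_tau(tau_T, lc_T, h), rho_cp_from_tau(tau_B, lc_B, h),
      v_B, v_S)))
    expect_equal(r1, r2, tolerance = 1e-10)
  }
})

test_that("end-to-end inversion recovers the sample heat capacity exactly without noise", {
  mod <- test_model(sample_ratio = 34)
  truth <- volumetric_heat_capacity(mod$sample$material)
  tr_B <- generate_trace(synthetic_spec(test_model()))
  tr_T <- generate_trace(synthetic_spec(mod))
  fit_B <- fit_exponential(tr_B)
  fit_T <- fit_exponential(tr_T)
  est <- estimate_heat_capacity(fit_B, fit_T, mod)
  expect_true(est$valid)
  expect_equal(est$rho_cp_S, truth, tolerance = 1e-6)
  # the two algebraic routes agree to roundoff
  est2 <- estimate_heat_capacity(fit_B, fit_T, mod, method = "eq_mixture")
  expect_equal(est2$rho_cp_S, est$rho_cp_S, tolerance = 1e-10)
  # a supplied density converts to specific heat
  est3 <- estimate_heat_capacity(fit_B, fit_T, mod, density = 1100)
  expect_equal(est3$cp_S, truth / 1100, tolerance = 1e-6)
})

test_that("an effectively absent sample yields a flagged estimate", {
  mod <- test_model(sample_ratio = 34)
  tr <- generate_trace(synthetic_spec(test_model()))
  fit <- fit_exponential(tr)
  # identical calibration and loaded fits: tau_T = tau_B, nothing to invert
  est <- suppressWarnings(estimate_heat_capacity(fit, fit, mod))
  expect_false(est$valid)
  expect_true(any(grepl("not larger", est$reasons)))
})

test_that("the estimate standard error grows with the volume ratio", {
  rmse <- vapply(c(5, 34, 100), function(R) {
    run_recovery_experiment(test_model(sample_ratio = R), n_replicates = 10,
                            noise_sigma = 0.01, seed = 42)$summary$rmse
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("the lumped response is independent of the sample position", {
  geom <- test_beam()
  mk <- function(pos) {
    smp <- sample_spec(default_materials()$yeast, 5e-6, 2e-6, 5e-6,
                       position_on_beam = pos,
                       volume_override = beam_volume(geom) / 34)
    beam_model(geom, environment_spec(), irradiation(), sample = smp)
  }
  tr_mid <- generate_trace(synthetic_spec(mk(300e-6)))
  tr_tip <- generate_trace(synthetic_spec(mk(550e-6)))
  expect_identical(tr_mid$tip, tr_tip$tip)
})
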