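#' Specification of a synthetic deflection trace
#'
#' Everything needed to generate a reproducible simulated measurement: a
#' forward-model configuration, a sampling grid, a Gaussian noise level and a
#' seed. The noise standard deviation is expressed as a fraction of the
#' noiseless trace range so it is invariant to the physical scale of the
#' deflection.
#'
#' @param model A [beam_model()] (with or without a sample).
#' @param noise_sigma Noise sd as a fraction of the noiseless trace range
#'   (>= 0).
#' @param n_points Number of samples (>= 4), default 500.
#' @param t_end Record length, s (> 0), default 0.5.
#' @param seed Integer seed; the same spec always yields a bit-identical
#'   trace.
#' @return Object of class `bmc_synth_spec`.
#' @export
synthetic_spec <- function(model, noise_sigma = 0, n_points = 500,
                           t_end = 0.5, seed = 1L) {
  stopifnot(inherits(model, "bmc_model"))
  check_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)
  check_scalar(t_end, "t_end", positive = TRUE)
  if (n_points < 4L) stop_domain("`n_points` must be >= 4")
  structure(list(model = model, noise_sigma = noise_sigma,
                 n_points = as.integer(n_points), t_end = t_end,
                 seed = as.integer(seed)),
            class = "bmc_synth_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic deflection trace
#'
#' Runs the forward model (lumped by default; the lumped path uses the exact
#' exponential step of the linear energy balance) and the bimorph mechanics
#' on a uniform grid, then adds i.i.d. Gaussian noise scaled to the noiseless
#' trace range. The seed and generation settings are stamped into the trace's
#' `meta`; randomness never touches the caller's RNG state.
#'
#' @param spec A [synthetic_spec()].
#' @param thermal_model `"lumped"` or `"distributed"`.
#' @return A [as_deflection_trace()] object.
#' @export
generate_trace <- function(spec, thermal_model = c("lumped", "distributed")) {
  stopifnot(inherits(spec, "bmc_synth_spec"))
  thermal_model <- match.arg(thermal_model)
  times <- seq(0, spec$t_end, length.out = spec$n_points)
  thermal <- if (thermal_model == "lumped")
    simulate_lumped_ode(spec$model, times, method = "exponential")
  else
    simulate_distributed_1d(spec$model, times)
  tr <- deflection_trace(thermal, spec$model)
  tip <- tr$tip
  if (spec$noise_sigma > 0) {
    rng <- diff(range(tip))
    noise <- with_seed(spec$seed,
                       rnorm(length(tip), sd = spec$noise_sigma * rng))
    tip <- tip + noise
  }
  as_deflection_trace(times, tip, meta = list(
    seed = spec$seed, noise_sigma = spec$noise_sigma,
    thermal_model = thermal_model,
    has_sample = !is.null(spec$model$sample)))
}

strip_sample <- function(model) {
  beam_model(model$geometry, model$environment, model$irradiation,
             sample = NULL,
             volume_ratio_override = model$volume_ratio_override,
             lc_beam_override = model$lc_beam_override)
}

#' Replicated generate-fit-invert recovery experiment
#'
#' For each replicate: simulate a bare-beam calibration trace and a loaded
#' trace (independent noise), fit both exponentials, and invert to the sample
#' volumetric heat capacity. Reports per-replicate estimates and a summary
#' (bias, RMSE, median, IQR, and coverage of the one-standard-error
#' interval against the known truth). Replicates with flagged estimates are
#' recorded, not dropped.
#'
#' @param model A [beam_model()] including the sample whose heat capacity is
#'   the recovery target.
#' @param n_replicates Number of replicates.
#' @param noise_sigma Noise level (fraction of trace range) for both traces.
#' @param n_points,t_end Sampling grid, as in [synthetic_spec()].
#' @param seed Base seed; replicate r uses seeds `seed + 2r - 2` and
#'   `seed + 2r - 1` for the two traces.
#' @param ... Passed on to [estimate_heat_capacity()] (e.g. `method`).
#' @return Object of class `bmc_recovery`: list with `replicates` (data
#'   frame: replicate, tau_B, tau_T, rho_cp_S, se, rel_error, valid,
#'   covered) and `summary` (one-row data frame: n, n_valid, truth,
#'   median, iqr, bias, rel_bias, rmse, coverage, median_rel_error).
#' @export
run_recovery_experiment <- function(model, n_replicates = 1, noise_sigma = 0,
                                    n_points = 500, t_end = 0.5, seed = 1L,
                                    ...) {
  stopifnot(inherits(model, "bmc_model"))
  if (is.null(model$sample))
    stop_domain("`model` must include a sample")
  truth <- volumetric_heat_capacity(model$sample$material)
  model_B <- strip_sample(model)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s_B <- as.integer(seed + 2L * (r - 1L))
    s_T <- as.integer(seed + 2L * (r - 1L) + 1L)
    tr_B <- generate_trace(synthetic_spec(model_B, noise_sigma, n_points,
                                          t_end, s_B))
    tr_T <- generate_trace(synthetic_spec(model, noise_sigma, n_points,
                                          t_end, s_T))
    fit_B <- fit_exponential(tr_B)
    fit_T <- fit_exponential(tr_T)
    est <- estimate_heat_capacity(fit_B, fit_T, model, ...)
    covered <- is.finite(est$se_rho_cp_S) && est$se_rho_cp_S > 0 &&
      abs(est$rho_cp_S - truth) <= est$se_rho_cp_S
    rows[[r]] <- data.frame(
      replicate = r, tau_B = fit_B$tau, tau_T = fit_T$tau,
      rho_cp_S = est$rho_cp_S, se = est$se_rho_cp_S,
      rel_error = (est$rho_cp_S - truth) / truth,
      valid = est$valid, covered = covered)
  }
  reps <- do.call(rbind, rows)
  est_v <- reps$rho_cp_S
  summary <- data.frame(
    n = n_replicates, n_valid = sum(reps$valid), truth = truth,
    median = median(est_v), iqr = unname(diff(quantile(est_v, c(.25, .75)))),
    bias = mean(est_v) - truth, rel_bias = (mean(est_v) - truth) / truth,
    rmse = sqrt(mean((est_v - truth)^2)),
    coverage = mean(reps$covered),
    median_rel_error = (median(est_v) - truth) / truth)
  structure(list(replicates = reps, summary = summary, truth = truth),
            class = "bmc_recovery")
}

#' @export
print.bmc_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<bmc_recovery> %d replicates (%d valid), truth = %.5g J/(m^3 K)\n",
              s$n, s$n_valid, s$truth))
  cat(sprintf("  median = %.5g (rel err %.3g%%), rmse = %.4g, 1-se coverage = %.2f\n",
              s$median, 100 * s$median_rel_error, s$rmse, s$coverage))
  invisible(x)
}

#' Bundled published-reference configuration
#'
#' The configuration of the published reference scenario this package
#' models: a 600 x 76 um silicon-nitride beam, 1 um thick, with a 500 nm
#' aluminium underlayer; 500 W/m^2 absorbed flux left on; free convection at
#' h = 20 W/(m^2 K) (both faces by default); and a yeast-like sample, 5 um
#' long and 2 um high, centred on the beam. The prescribed beam-to-sample
#' volume ratio (34) and the characteristic lengths (beam 1.0 um, sample
#' 1.1 um) are pinned as overrides because they are quoted values that do not
#' follow from the box dimensions (see [reference_demo()]).
#'
#' @param materials Material table, by default [default_materials()].
#' @return A [beam_model()] including the sample.
#' @export
reference_profile <- function(materials = default_materials()) {
  stack <- layer_stack(materials$si3n4, materials$aluminium,
                       t_top = 1e-6, t_bottom = 0.5e-6)
  geom <- beam_geometry(600e-6, 76e-6, stack)
  env <- environment_spec(t_ambient = 293.15, h_conv = 20,
                          convection_sides = "both")
  irr <- irradiation(absorbed_flux = 500, t_on = 0, duration = Inf)
  smp <- sample_spec(materials$yeast, length = 5e-6, height = 2e-6,
                     width = 5e-6, position_on_beam = 300e-6,
                     lc_override = 1.1e-6)
  beam_model(geom, env, irr, sample = smp,
             volume_ratio_override = 34, lc_beam_override = 1.0e-6)
}

#' Reproduce and audit the published reference numbers
#'
#' Recomputes the headline quantities of the reference scenario from the
#' bundled configuration -- the sample Biot number, the beam characteristic
#' length, the lumped time constant and steady temperature rise, the steady
#' tip deflection -- and then evaluates the published inversion shortcut on
#' the published fitted time constants (calibration 66.5 ms, loaded
#' 69.3 ms, V_B/V_S = 34, Lc ratio 1.1/1.0). The shortcut evaluates to
#' about 181 ms, whereas the published sample time constant is 230 ms, and
#' the published specific heat (2.165 kJ/(kg K)) additionally requires a
#' mass density that is not part of the published inputs. Both published
#' values are therefore reported alongside the recomputed ones and flagged
#' as not derivable from the published inputs alone; the package reproduces
#' the formulas and does not tune constants toward the published numbers.
#'
#' @param quiet Suppress the printed table.
#' @return (Invisibly) a list with the computed and published values:
#'   `biot`, `lc_beam_m`, `tc_lumped_s`, `steady_rise_K`,
#'   `steady_tip_m`, `tau_calibration_s`, `tau_loaded_s` (published fit
#'   inputs), `tau_sample_shortcut_s`, `tau_sample_published_s`,
#'   `rho_cp_from_published_tau`, `cp_published_kJ_per_kgK`, and the
#'   flags `tau_sample_derivable`, `cp_derivable` (both `FALSE`).
#' @export
reference_demo <- function(quiet = FALSE) {
  model <- reference_profile()
  smp <- model$sample
  bi <- biot_number(model$environment$h_conv, smp$length,
                    smp$material$thermal_conductivity)
  g <- model$geometry
  lc_beam <- characteristic_length(g$length * g$width * g$stack$t_top,
                                   g$length * g$width)
  p <- lumped_params(model)
  rise <- p$t_inf - p$t0
  kappa <- curvature_from_dT(g$stack, rise)
  tip <- kappa * g$length^2 / 2
  # published fitted parameter sets (inputs, in instrument units)
  tau_B <- 66.5e-3; tau_T <- 69.3e-3
  tau_S <- sample_time_constant(tau_B, tau_T,
                                lc_B = model$lc_beam_override,
                                lc_S = smp$lc_override,
                                vb_over_vs = model$volume_ratio_override)
  tau_S_pub <- 0.230
  # published chain uses the single-face h = 20 W/m^2K
  rc_pub <- rho_cp_from_tau(tau_S_pub, smp$lc_override,
                            model$environment$h_conv)
  rc_shortcut <- rho_cp_from_tau(as.numeric(tau_S), smp$lc_override,
                                 model$environment$h_conv)
  out <- list(
    biot = as.numeric(bi), biot_lumped_valid = attr(bi, "lumped_valid"),
    lc_beam_m = lc_beam,
    tc_lumped_s = p$tc, steady_rise_K = rise, steady_tip_m = tip,
    tau_calibration_s = tau_B, tau_loaded_s = tau_T,
    tau_sample_shortcut_s = as.numeric(tau_S),
    tau_sample_published_s = tau_S_pub,
    rho_cp_shortcut = rc_shortcut,
    rho_cp_from_published_tau = rc_pub,
    cp_published_kJ_per_kgK = 2.165,
    tau_sample_derivable = FALSE, cp_derivable = FALSE)
  if (!quiet) {
    cat("Reference-scenario audit (computed from the bundled configuration)\n")
    cat(sprintf("  sample Biot number          : %.4g (lumped approximation %s)\n",
                out$biot, if (out$biot_lumped_valid) "valid" else "invalid"))
    cat(sprintf("  beam characteristic length  : %.3g um\n", lc_beam * 1e6))
    cat(sprintf("  lumped time constant        : %.3g ms\n", p$tc * 1e3))
    cat(sprintf("  steady temperature rise     : %.4g K\n", rise))
    cat(sprintf("  steady tip deflection       : %.4g um (published: 178 um;\n",
                tip * 1e6))
    cat("      order-of-magnitude anchor only -- depends on unpublished constants)\n")
    cat(sprintf("  shortcut sample time const. : %.4g ms (from published fits %.3g / %.3g ms,\n",
                as.numeric(tau_S) * 1e3, tau_B * 1e3, tau_T * 1e3))
    cat(sprintf("      V_B/V_S = %g, Lc ratio %.2g)\n",
                model$volume_ratio_override,
                smp$lc_override / model$lc_beam_override))
    cat(sprintf("  published sample time const.: %g ms  <-- NOT derivable from the\n",
                tau_S_pub * 1e3))
    cat("      published inputs via the shortcut formula (documented discrepancy)\n")
    cat(sprintf("  published specific heat     : %.4g kJ/(kg K)  <-- additionally requires\n",
                out$cp_published_kJ_per_kgK))
    cat("      an unpublished sample density; not derivable from deflection data alone\n")
  }
  invisible(out)
}
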