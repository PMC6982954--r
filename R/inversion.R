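#' Volume-weighted heat-capacity mixture
#'
#' Volumetric heat capacity of the combined beam + sample system:
#' `(rhoCp)_T = ((rhoCp)_B V_B + (rhoCp)_S V_S) / (V_B + V_S)`.
#'
#' @param rho_cp_B,rho_cp_S Volumetric heat capacities, J/(m^3 K).
#' @param v_B,v_S Volumes, m^3 (> 0).
#' @return Mixture volumetric heat capacity, J/(m^3 K).
#' @export
mixture_rho_cp <- function(rho_cp_B, rho_cp_S, v_B, v_S) {
  check_scalar(v_B, "v_B", positive = TRUE)
  check_scalar(v_S, "v_S", positive = TRUE)
  (rho_cp_B * v_B + rho_cp_S * v_S) / (v_B + v_S)
}

#' Invert the mixture rule for the sample heat capacity
#'
#' Exact algebraic inverse of [mixture_rho_cp()]:
#' `(rhoCp)_S = ((rhoCp)_T (V_B + V_S) - (rhoCp)_B V_B) / V_S`.
#' The result is the small difference of two nearly equal large terms when
#' `V_B >> V_S`; a warning is emitted when the cancellation amplifies input
#' error more than tenfold, and a nonpositive result is flagged invalid (via
#' the `valid` attribute) rather than returned silently.
#'
#' @param rho_cp_T Mixture volumetric heat capacity, J/(m^3 K).
#' @param rho_cp_B Beam volumetric heat capacity, J/(m^3 K).
#' @param v_B,v_S Volumes, m^3 (> 0).
#' @return Sample volumetric heat capacity, J/(m^3 K), with attribute
#'   `valid` (FALSE when the result is nonpositive).
#' @export
invert_mixture <- function(rho_cp_T, rho_cp_B, v_B, v_S) {
  check_scalar(v_B, "v_B", positive = TRUE)
  check_scalar(v_S, "v_S", positive = TRUE)
  big <- rho_cp_T * (v_B + v_S)
  small <- rho_cp_B * v_B
  num <- big - small
  if (num != 0 && (abs(big) + abs(small)) / abs(num) > 10)
    warning(sprintf(
      "large-number cancellation: error amplification ~%.3g-fold",
      (abs(big) + abs(small)) / abs(num)), call. = FALSE)
  out <- num / v_S
  if (out <= 0)
    warning("inverted sample heat capacity is nonpositive; estimate flagged invalid",
            call. = FALSE)
  structure(out, valid = out > 0)
}

#' Lumped time constant from volumetric heat capacity, and back
#'
#' For a convectively cooled lumped mass, `tau = rhoCp * Lc / h_eff` and
#' `rhoCp = tau * h_eff / Lc`. The two functions are mutual inverses by
#' construction.
#'
#' @param rho_cp Volumetric heat capacity, J/(m^3 K) (> 0).
#' @param tau Thermal time constant, s (> 0).
#' @param lc Characteristic heat-transfer length, m (> 0).
#' @param h_eff Effective heat-loss coefficient, W/(m^2 K) (> 0).
#' @return `tau_from_rho_cp()`: time constant, s. `rho_cp_from_tau()`:
#'   volumetric heat capacity, J/(m^3 K).
#' @export
tau_from_rho_cp <- function(rho_cp, lc, h_eff) {
  check_scalar(rho_cp, "rho_cp", positive = TRUE)
  check_scalar(lc, "lc", positive = TRUE)
  check_scalar(h_eff, "h_eff", positive = TRUE)
  rho_cp * lc / h_eff
}

#' @rdname tau_from_rho_cp
#' @export
rho_cp_from_tau <- function(tau, lc, h_eff) {
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(lc, "lc", positive = TRUE)
  check_scalar(h_eff, "h_eff", positive = TRUE)
  tau * h_eff / lc
}

#' Sample thermal time constant from calibration and loaded fits
#'
#' Combines the mixture inversion with the per-object time-constant relation
#' (each body's `tau = rhoCp Lc / h`, `h` common to both runs, so `h`
#' cancels):
#' `tau_S = Lc_S * ((tau_T / Lc_T) (1 + R) - (tau_B / Lc_B) R)`,
#' where `R = V_B / V_S`. With `lc_T = lc_B` this reduces to the shortcut
#' `tau_S = (Lc_S / Lc_B) * (tau_T + R (tau_T - tau_B))`, which is the
#' default. Note the shortcut treats the loaded system's characteristic
#' length as the bare beam's; passing the volume-consistent
#' `lc_T = (V_B + V_S) / A` instead makes the chain an exact inverse of the
#' lumped forward model (see the methods vignette).
#'
#' @param tau_B Calibration (bare-beam) time constant, s (> 0).
#' @param tau_T Loaded (beam + sample) time constant, s (> 0).
#' @param lc_B,lc_S Beam and sample characteristic lengths, m (> 0).
#' @param vb_over_vs Volume ratio V_B / V_S (> 0).
#' @param lc_T Characteristic length attributed to the loaded system, m;
#'   defaults to `lc_B`.
#' @return Sample time constant, s, with attribute `valid` (FALSE when
#'   nonpositive).
#' @export
sample_time_constant <- function(tau_B, tau_T, lc_B, lc_S, vb_over_vs,
                                 lc_T = lc_B) {
  check_scalar(tau_B, "tau_B", positive = TRUE)
  check_scalar(tau_T, "tau_T", positive = TRUE)
  check_scalar(lc_B, "lc_B", positive = TRUE)
  check_scalar(lc_S, "lc_S", positive = TRUE)
  check_scalar(vb_over_vs, "vb_over_vs", positive = TRUE)
  check_scalar(lc_T, "lc_T", positive = TRUE)
  R <- vb_over_vs
  out <- lc_S * ((tau_T / lc_T) * (1 + R) - (tau_B / lc_B) * R)
  if (out <= 0)
    warning("sample time constant is nonpositive; flagged invalid", call. = FALSE)
  structure(out, valid = out > 0)
}

#' Estimate the sample heat capacity from a calibration and a loaded fit
#'
#' The full inversion chain: take the fitted time constants of the bare-beam
#' (calibration) and sample-loaded runs, form the sample time constant via
#' the generalised mixture relation ([sample_time_constant()]), and convert
#' to volumetric heat capacity via `rhoCp = tau h_eff / Lc`
#' ([rho_cp_from_tau()]). Fit standard errors on the two time constants are
#' propagated first-order to a standard error on `(rhoCp)_S`. Specific heat
#' is reported only when a sample mass density is supplied; it is not
#' derivable from deflection data alone.
#'
#' Characteristic lengths default to volume/area values computed from the
#' model geometry: `Lc_B = V_B / A` (A the beam plan area), `Lc_S` = sample
#' volume over footprint, and -- crucially -- `Lc_T = (V_B + V_S) / A` for
#' the loaded system, which makes the chain an exact inverse of the lumped
#' forward model. Overrides on the model (`lc_beam_override`, the sample's
#' `lc_override`) are honoured; `lc_T = lc_B` reproduces the shortcut form
#' instead (biased against the physical forward model; see the vignette).
#'
#' The two `method`s are algebraically identical routes through the same
#' relations (`"eq_mixture"` goes explicitly through the mixture inversion,
#' `"eq_shortcut"` through [sample_time_constant()]); both are kept so the
#' equivalence can be asserted in tests.
#'
#' @param fit_B Calibration [fit_exponential()] result.
#' @param fit_T Loaded [fit_exponential()] result.
#' @param model A [beam_model()] that includes the sample.
#' @param density Optional sample mass density, kg/m^3, for specific heat.
#' @param lc_T Optional loaded-system characteristic length, m.
#' @param method `"eq_shortcut"` (default) or `"eq_mixture"`.
#' @return Object of class `bmc_estimate` with fields `tau_B`, `tau_T`,
#'   `tau_S` (s), `lc_B`, `lc_S`, `lc_T` (m), `volume_ratio`, `rho_cp_S`
#'   and `se_rho_cp_S` (J/(m^3 K)), `cp_S` (J/(kg K) or `NA`), `h_eff`,
#'   `method`, `valid` and `reasons`.
#' @export
estimate_heat_capacity <- function(fit_B, fit_T, model, density = NULL,
                                   lc_T = NULL,
                                   method = c("eq_shortcut", "eq_mixture")) {
  stopifnot(inherits(fit_B, "bmc_fit"), inherits(fit_T, "bmc_fit"),
            inherits(model, "bmc_model"))
  method <- match.arg(method)
  if (is.null(model$sample))
    stop_domain("`model` must include the sample that was loaded")
  reasons <- character(0)
  if (!fit_B$converged) reasons <- c(reasons, "calibration fit did not converge")
  if (!fit_T$converged) reasons <- c(reasons, "loaded fit did not converge")
  g <- model$geometry
  A <- g$length * g$width
  v_B <- beam_volume(g)
  v_S <- sample_volume(model$sample)
  R <- model$volume_ratio_override %||% (v_B / v_S)
  if (!is.null(model$volume_ratio_override)) v_S <- v_B / R
  lc_B <- model$lc_beam_override %||% (v_B / A)
  lc_S <- model$sample$lc_override %||%
    (v_S / (model$sample$length * model$sample$width))
  lc_T <- lc_T %||% ((v_B + v_S) / A)
  h_eff <- h_effective(model$environment)
  if (h_eff <= 0) stop_domain("h_eff must be > 0 to convert tau to heat capacity")
  tau_B <- fit_B$tau; tau_T <- fit_T$tau
  if (tau_T <= tau_B)
    reasons <- c(reasons,
                 "loaded time constant is not larger than the calibration's")
  tau_S <- suppressWarnings(
    sample_time_constant(tau_B, tau_T, lc_B, lc_S, R, lc_T = lc_T))
  if (method == "eq_mixture") {
    rc_T <- rho_cp_from_tau(tau_T, lc_T, h_eff)
    rc_B <- rho_cp_from_tau(tau_B, lc_B, h_eff)
    rc_S <- suppressWarnings(invert_mixture(rc_T, rc_B, v_B, v_S))
  } else {
    rc_S <- if (tau_S > 0) rho_cp_from_tau(as.numeric(tau_S), lc_S, h_eff)
            else structure(as.numeric(tau_S) * h_eff / lc_S, valid = FALSE)
  }
  if (!isTRUE(attr(tau_S, "valid")))
    reasons <- c(reasons, "nonpositive sample time constant")
  if (as.numeric(rc_S) <= 0)
    reasons <- c(reasons, "nonpositive sample heat capacity")
  # first-order error propagation from the two fitted time constants
  se_tau_B <- fit_B$se[["tau"]]; se_tau_T <- fit_T$se[["tau"]]
  d_T <- h_eff * (1 + R) / lc_T
  d_B <- -h_eff * R / lc_B
  se_rc <- if (is.finite(se_tau_B) && is.finite(se_tau_T))
    sqrt((d_T * se_tau_T)^2 + (d_B * se_tau_B)^2) else NA_real_
  cp_S <- if (!is.null(density)) {
    check_scalar(density, "density", positive = TRUE)
    as.numeric(rc_S) / density
  } else NA_real_
  structure(list(
    tau_B = tau_B, tau_T = tau_T, tau_S = as.numeric(tau_S),
    lc_B = lc_B, lc_S = lc_S, lc_T = lc_T, volume_ratio = R,
    rho_cp_S = as.numeric(rc_S), se_rho_cp_S = se_rc, cp_S = cp_S,
    h_eff = h_eff, method = method,
    valid = length(reasons) == 0L, reasons = reasons),
    class = "bmc_estimate")
}

#' @export
print.bmc_estimate <- function(x, ...) {
  cat(sprintf("<bmc_estimate> (%s)%s\n", x$method,
              if (x$valid) "" else " INVALID"))
  cat(sprintf("  tau_B = %.5g ms, tau_T = %.5g ms -> tau_S = %.5g ms\n",
              x$tau_B * 1e3, x$tau_T * 1e3, x$tau_S * 1e3))
  cat(sprintf("  (rhoCp)_S = %.5g J/(m^3 K) (se %.3g), V_B/V_S = %.4g\n",
              x$rho_cp_S, x$se_rho_cp_S, x$volume_ratio))
  if (is.finite(x$cp_S))
    cat(sprintf("  cp_S = %.5g kJ/(kg K)\n", x$cp_S / 1000))
  if (length(x$reasons))
    cat("  reasons:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}
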