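#' Dimensionless curvature coefficient of a two-layer beam
#'
#' With thickness ratio `m = t_top / t_bottom` and modulus ratio
#' `n = E_top / E_bottom`:
#' `K = 4 + 6 m + 4 m^2 + n m^3 + 1 / (n m)`.
#' K appears in the denominator of the thermally induced curvature and
#' encodes how the layer stiffnesses share the thermal misfit strain.
#'
#' @param stack A [layer_stack()].
#' @return K (dimensionless; 16 for identical layers).
#' @export
curvature_coefficient_K <- function(stack) {
  stopifnot(inherits(stack, "bmc_stack"))
  m <- stack$t_top / stack$t_bottom
  n <- stack$top$youngs_modulus / stack$bottom$youngs_modulus
  4 + 6 * m + 4 * m^2 + n * m^3 + 1 / (n * m)
}

#' Thermally induced bimorph curvature
#'
#' Curvature of the two-layer beam for a uniform temperature change `dT`:
#' `kappa = 6 (alpha_bottom - alpha_top) (t_top + t_bottom) / (t_bottom^2 K) * dT`.
#'
#' Sign convention: the deflection axis z points toward the top (structural)
#' layer, so heating a beam whose *bottom* layer expands more produces
#' positive curvature and a positive tip deflection. For the default
#' nitride-over-aluminium stack, heating deflects the tip upward.
#'
#' @param stack A [layer_stack()].
#' @param dT Temperature change above the zero-deflection temperature, K;
#'   vectorised.
#' @return Curvature, 1/m.
#' @seealso [timoshenko_curvature()] for the classical bimetal-strip form of
#'   the same result, used as an independent oracle in the tests.
#' @export
curvature_from_dT <- function(stack, dT) {
  stopifnot(inherits(stack, "bmc_stack"))
  d_alpha <- stack$bottom$thermal_expansion - stack$top$thermal_expansion
  K <- curvature_coefficient_K(stack)
  6 * d_alpha * (stack$t_top + stack$t_bottom) / (stack$t_bottom^2 * K) * dT
}

#' Classical bimetal-strip curvature (independent oracle)
#'
#' Timoshenko's bimetal thermostat curvature,
#' `kappa = 6 dAlpha dT (1 + m)^2 / (t_total * (3 (1 + m)^2 +
#' (1 + m n) (m^2 + 1 / (m n))))`,
#' with `m = t_top / t_bottom`, `n = E_top / E_bottom`,
#' `dAlpha = alpha_bottom - alpha_top` and the same sign convention as
#' [curvature_from_dT()]. The two expressions are algebraically identical;
#' this one is kept as an independently coded cross-check.
#'
#' @inheritParams curvature_from_dT
#' @return Curvature, 1/m.
#' @export
timoshenko_curvature <- function(stack, dT) {
  stopifnot(inherits(stack, "bmc_stack"))
  m <- stack$t_top / stack$t_bottom
  n <- stack$top$youngs_modulus / stack$bottom$youngs_modulus
  d_alpha <- stack$bottom$thermal_expansion - stack$top$thermal_expansion
  t_tot <- stack$t_top + stack$t_bottom
  denom <- 3 * (1 + m)^2 + (1 + m * n) * (m^2 + 1 / (m * n))
  6 * d_alpha * dT * (1 + m)^2 / (t_tot * denom)
}

#' Integrate a curvature field to a deflection profile
#'
#' Double cumulative trapezoidal integration of `d2z/dx2 = kappa(x)` with
#' clamped-anchor conditions `z(0) = 0`, `z'(0) = 0`. Exact for curvature
#' fields up to linear in x; second-order accurate otherwise.
#'
#' @param x Node positions from the anchor, m, strictly increasing, first
#'   node at 0.
#' @param kappa Curvature at each node, 1/m.
#' @return Object of class `bmc_deflection_profile` with fields `x`, `z`
#'   (deflection per node, m), `tip_deflection` (m) and `sign_convention`.
#' @export
integrate_deflection <- function(x, kappa) {
  if (length(x) < 2L || any(diff(x) <= 0))
    stop_domain("`x` must be strictly increasing")
  if (length(kappa) != length(x))
    stop_domain("`kappa` must have one value per node")
  slope <- pracma::cumtrapz(x, kappa)[, 1]
  z <- pracma::cumtrapz(x, slope)[, 1]
  structure(list(x = x, z = z, tip_deflection = z[length(z)],
                 sign_convention = "positive toward the top (structural) layer"),
            class = "bmc_deflection_profile")
}

#' @export
print.bmc_deflection_profile <- function(x, ...) {
  cat(sprintf("<bmc_deflection_profile> %d nodes over %.3g um, tip = %.4g um (%s)\n",
              length(x$x), max(x$x) * 1e6, x$tip_deflection * 1e6,
              x$sign_convention))
  invisible(x)
}

#' Tip-deflection trace from a thermal trace
#'
#' Maps simulated temperatures to tip displacement. For a lumped trace the
#' uniform-temperature closed form `tip = kappa(dT) L^2 / 2` is used; for a
#' distributed trace the local curvature is integrated along the beam at each
#' time point. Because curvature is linear in temperature change, the tip
#' trace is an exact linear map of the temperature trace.
#'
#' @param thermal A [thermal_trace()].
#' @param model The [beam_model()] that produced it.
#' @param meta Optional provenance list stored on the result.
#' @return Object of class `bmc_deflection_trace` with fields `times` (s),
#'   `tip` (m) and `meta`.
#' @export
deflection_trace <- function(thermal, model, meta = list()) {
  stopifnot(inherits(thermal, "bmc_thermal_trace"),
            inherits(model, "bmc_model"))
  g <- model$geometry
  t0 <- if (is.finite(thermal$t_ambient)) thermal$t_ambient
        else if (thermal$model == "lumped") thermal$temperature[1]
        else mean(thermal$temperature[1, ])
  if (thermal$model == "lumped") {
    kap <- curvature_from_dT(g$stack, thermal$temperature - t0)
    tip <- kap * g$length^2 / 2
  } else {
    tip <- apply(thermal$temperature, 1L, function(row) {
      kap <- curvature_from_dT(g$stack, row - t0)
      integrate_deflection(thermal$x, kap)$tip_deflection
    })
  }
  meta$thermal_model <- thermal$model
  meta$sign_convention <- "positive toward the top (structural) layer"
  as_deflection_trace(thermal$times, tip, meta = meta)
}
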