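#' Material thermophysical and elastic constants
#'
#' A material is described by the constants the thermal and mechanical models
#' need: density, specific heat, thermal conductivity, linear thermal
#' expansion coefficient and Young's modulus. All values are SI.
#'
#' @param name Short material name.
#' @param density Mass density, kg/m^3 (> 0).
#' @param specific_heat Specific heat capacity at constant pressure, J/(kg K)
#'   (> 0).
#' @param thermal_conductivity Thermal conductivity, W/(m K) (> 0).
#' @param thermal_expansion Linear thermal expansion coefficient, 1/K. May be
#'   any real number; positive for the materials shipped with the package.
#' @param youngs_modulus Young's modulus, Pa (> 0). Irrelevant for a soft
#'   sample that does not contribute to the bimorph stiffness; defaults to
#'   1 Pa so purely thermal materials can be declared tersely.
#' @return An object of class `bmc_material`.
#' @seealso [default_materials()] for the bundled handbook table.
#' @export
#' @examples
#' al <- bmc_material("aluminium", 2700, 900, 237,
#'                    thermal_expansion = 23.1e-6, youngs_modulus = 70e9)
#' volumetric_heat_capacity(al)
bmc_material <- function(name, density, specific_heat, thermal_conductivity,
                         thermal_expansion = 0, youngs_modulus = 1) {
  if (!is.character(name) || length(name) != 1L)
    stop_domain("`name` must be a single string")
  check_scalar(density, "density", positive = TRUE)
  check_scalar(specific_heat, "specific_heat", positive = TRUE)
  check_scalar(thermal_conductivity, "thermal_conductivity", positive = TRUE)
  check_scalar(thermal_expansion, "thermal_expansion")
  check_scalar(youngs_modulus, "youngs_modulus", positive = TRUE)
  structure(
    list(name = name, density = density, specific_heat = specific_heat,
         thermal_conductivity = thermal_conductivity,
         thermal_expansion = thermal_expansion,
         youngs_modulus = youngs_modulus),
    class = "bmc_material")
}

#' @export
print.bmc_material <- function(x, ...) {
  cat(sprintf(
    "<bmc_material> %s: rho=%g kg/m^3, Cp=%g J/(kg K), k=%g W/(m K), alpha=%g 1/K, E=%g Pa\n",
    x$name, x$density, x$specific_heat, x$thermal_conductivity,
    x$thermal_expansion, x$youngs_modulus))
  invisible(x)
}

#' Volumetric heat capacity of a material
#'
#' @param material A [bmc_material()].
#' @return rho * Cp in J/(m^3 K).
#' @export
volumetric_heat_capacity <- function(material) {
  stopifnot(inherits(material, "bmc_material"))
  material$density * material$specific_heat
}

#' Bundled handbook material table
#'
#' Default constants for the structural layer (silicon nitride), the metal
#' coating (aluminium) and a yeast-like biological sample. The nitride and
#' aluminium values are standard room-temperature handbook values for
#' LPCVD Si3N4 and bulk Al. The yeast entry uses a water-like density, the
#' literature specific heat of yeast (2.17 kJ/(kg K)) and the low effective
#' conductivity (0.03 W/(m K)) used when checking the sample's Biot number;
#' its expansion coefficient and modulus are irrelevant to the models (the
#' sample adds heat capacity, not stiffness) and are left at neutral values.
#' Every entry can be overridden by constructing a replacement
#' [bmc_material()].
#'
#' @return Named list with elements `si3n4`, `aluminium`, `yeast`.
#' @export
#' @examples
#' default_materials()$si3n4
default_materials <- function() {
  list(
    si3n4 = bmc_material("Si3N4", density = 3100, specific_heat = 700,
                         thermal_conductivity = 20,
                         thermal_expansion = 2.3e-6,
                         youngs_modulus = 250e9),
    aluminium = bmc_material("Al", density = 2700, specific_heat = 900,
                             thermal_conductivity = 237,
                             thermal_expansion = 23.1e-6,
                             youngs_modulus = 70e9),
    yeast = bmc_material("yeast", density = 1100, specific_heat = 2170,
                         thermal_conductivity = 0.03,
                         thermal_expansion = 0, youngs_modulus = 1)
  )
}

#' Two-layer stack of a bimaterial beam
#'
#' @param top Structural layer [bmc_material()] (irradiated side).
#' @param bottom Coating layer [bmc_material()].
#' @param t_top,t_bottom Layer thicknesses, m (> 0).
#' @return Object of class `bmc_stack`.
#' @export
layer_stack <- function(top, bottom, t_top, t_bottom) {
  stopifnot(inherits(top, "bmc_material"), inherits(bottom, "bmc_material"))
  check_scalar(t_top, "t_top", positive = TRUE)
  check_scalar(t_bottom, "t_bottom", positive = TRUE)
  structure(list(top = top, bottom = bottom, t_top = t_top,
                 t_bottom = t_bottom),
            class = "bmc_stack")
}

total_thickness <- function(stack) stack$t_top + stack$t_bottom

#' Cantilever beam geometry
#'
#' @param length Beam length, m (> 0). A warning is issued when the beam is
#'   not slender (length < 10x total thickness), since both the thermal and
#'   the mechanical models assume a thin beam.
#' @param width Beam width, m (> 0).
#' @param stack A [layer_stack()].
#' @return Object of class `bmc_geometry`.
#' @export
beam_geometry <- function(length, width, stack) {
  check_scalar(length, "length", positive = TRUE)
  check_scalar(width, "width", positive = TRUE)
  stopifnot(inherits(stack, "bmc_stack"))
  if (length < 10 * total_thickness(stack))
    warning("beam is not slender: length < 10 * total thickness", call. = FALSE)
  structure(list(length = length, width = width, stack = stack),
            class = "bmc_geometry")
}

#' Sample resting on the beam
#'
#' The sample is modelled as a box of the given material sitting on the beam
#' surface. It couples to the beam purely through added heat capacity (it is
#' assumed isothermal with the beam, which the sample Biot number justifies);
#' it contributes no stiffness.
#'
#' @param material A [bmc_material()].
#' @param length,height,width Box dimensions, m (> 0). `width` defaults to
#'   `length` (a roughly isometric cell).
#' @param position_on_beam Centre coordinate of the sample along the beam
#'   axis, m, measured from the anchor.
#' @param volume_override Optional volume, m^3, replacing
#'   `length*height*width`. Used when the beam-to-sample volume ratio is
#'   prescribed rather than derived from box dimensions.
#' @param lc_override Optional characteristic heat-transfer length, m,
#'   replacing volume / footprint-area.
#' @return Object of class `bmc_sample`.
#' @export
sample_spec <- function(material, length, height, width = length,
                        position_on_beam = 0, volume_override = NULL,
                        lc_override = NULL) {
  stopifnot(inherits(material, "bmc_material"))
  check_scalar(length, "length", positive = TRUE)
  check_scalar(height, "height", positive = TRUE)
  check_scalar(width, "width", positive = TRUE)
  check_scalar(position_on_beam, "position_on_beam", nonneg = TRUE)
  if (!is.null(volume_override))
    check_scalar(volume_override, "volume_override", positive = TRUE)
  if (!is.null(lc_override))
    check_scalar(lc_override, "lc_override", positive = TRUE)
  structure(list(material = material, length = length, height = height,
                 width = width, position_on_beam = position_on_beam,
                 volume_override = volume_override,
                 lc_override = lc_override),
            class = "bmc_sample")
}

#' Thermal environment of the beam
#'
#' @param t_ambient Ambient temperature, K (> 0).
#' @param h_conv Convective heat transfer coefficient, W/(m^2 K) (>= 0).
#' @param convection_sides `"both"` (default) or `"one"`: whether convective
#'   loss acts on both faces of the beam or only the top face. The effective
#'   coefficient is `h_conv` times the number of faces.
#' @param include_radiation Add a linearised radiative loss
#'   4*emissivity*sigma*T_ambient^3 per convecting face. Off by default: for
#'   the few-kelvin rises of interest the radiative term is small and the
#'   reference scenario neglects it.
#' @param emissivity Surface emissivity in `[0, 1]`, used only when radiation
#'   is enabled.
#' @return Object of class `bmc_environment`.
#' @export
environment_spec <- function(t_ambient = 293.15, h_conv = 20,
                             convection_sides = c("both", "one"),
                             include_radiation = FALSE, emissivity = 0.9) {
  check_scalar(t_ambient, "t_ambient", positive = TRUE)
  check_scalar(h_conv, "h_conv", nonneg = TRUE)
  convection_sides <- match.arg(convection_sides)
  check_scalar(emissivity, "emissivity")
  if (emissivity < 0 || emissivity > 1)
    stop_domain("`emissivity` must lie in [0, 1]")
  structure(list(t_ambient = t_ambient, h_conv = h_conv,
                 convection_sides = convection_sides,
                 include_radiation = isTRUE(include_radiation),
                 emissivity = emissivity),
            class = "bmc_environment")
}

#' Optical irradiation step
#'
#' A uniform absorbed flux over the whole beam surface, switched on at
#' `t_on` for `duration` seconds (use `Inf` for a laser left on). The flux is
#' the *absorbed* power density; absorption physics (wavelength, reflectivity)
#' is outside the model.
#'
#' @param absorbed_flux Absorbed flux q_s, W/m^2 (>= 0).
#' @param t_on Switch-on time, s (>= 0).
#' @param duration On-time, s (> 0, may be `Inf`).
#' @return Object of class `bmc_irradiation`.
#' @export
irradiation <- function(absorbed_flux = 500, t_on = 0, duration = Inf) {
  check_scalar(absorbed_flux, "absorbed_flux", nonneg = TRUE)
  check_scalar(t_on, "t_on", nonneg = TRUE)
  if (!(is.numeric(duration) && length(duration) == 1L && duration > 0))
    stop_domain("`duration` must be > 0 (possibly Inf)")
  structure(list(absorbed_flux = absorbed_flux, t_on = t_on,
                 duration = duration),
            class = "bmc_irradiation")
}

#' Full forward-model configuration
#'
#' Bundles geometry, environment, irradiation and (optionally) a sample into
#' the configuration every simulation and inversion consumes.
#'
#' @param geometry A [beam_geometry()].
#' @param environment A [environment_spec()].
#' @param irradiation A [irradiation()].
#' @param sample Optional [sample_spec()]; `NULL` for a bare calibration beam.
#' @param volume_ratio_override Optional prescribed beam-to-sample volume
#'   ratio V_B/V_S used by [volume_ratio()] instead of a geometric convention.
#' @param lc_beam_override Optional beam characteristic length, m, replacing
#'   beam volume / plan area in the inversion.
#' @return Object of class `bmc_model`.
#' @export
beam_model <- function(geometry, environment = environment_spec(),
                       irradiation = bmcal::irradiation(), sample = NULL,
                       volume_ratio_override = NULL,
                       lc_beam_override = NULL) {
  stopifnot(inherits(geometry, "bmc_geometry"),
            inherits(environment, "bmc_environment"),
            inherits(irradiation, "bmc_irradiation"))
  if (!is.null(sample)) {
    stopifnot(inherits(sample, "bmc_sample"))
    if (sample$position_on_beam > geometry$length)
      stop_domain("sample position lies beyond the beam tip")
  }
  if (!is.null(volume_ratio_override))
    check_scalar(volume_ratio_override, "volume_ratio_override", positive = TRUE)
  if (!is.null(lc_beam_override))
    check_scalar(lc_beam_override, "lc_beam_override", positive = TRUE)
  structure(list(geometry = geometry, environment = environment,
                 irradiation = irradiation, sample = sample,
                 volume_ratio_override = volume_ratio_override,
                 lc_beam_override = lc_beam_override),
            class = "bmc_model")
}

#' @export
print.bmc_model <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<bmc_model> beam %g x %g um, layers %s %g um / %s %g um\n",
              g$length * 1e6, g$width * 1e6,
              g$stack$top$name, g$stack$t_top * 1e6,
              g$stack$bottom$name, g$stack$t_bottom * 1e6))
  cat(sprintf("  environment: T_amb=%g K, h=%g W/m^2K (%s side%s)%s\n",
              x$environment$t_ambient, x$environment$h_conv,
              x$environment$convection_sides,
              if (x$environment$convection_sides == "both") "s" else "",
              if (x$environment$include_radiation) ", +linearised radiation" else ""))
  cat(sprintf("  irradiation: %g W/m^2 from t=%g s for %g s\n",
              x$irradiation$absorbed_flux, x$irradiation$t_on,
              x$irradiation$duration))
  if (!is.null(x$sample))
    cat(sprintf("  sample: %s, %g x %g x %g um at x=%g um\n",
                x$sample$material$name, x$sample$length * 1e6,
                x$sample$height * 1e6, x$sample$width * 1e6,
                x$sample$position_on_beam * 1e6))
  invisible(x)
}

#' Effective heat-loss coefficient
#'
#' Convective coefficient times the number of convecting faces, plus the
#' linearised radiative conductance 4*emissivity*sigma*T_amb^3 per face when
#' radiation is enabled.
#'
#' @param env A [environment_spec()].
#' @return Effective coefficient, W/(m^2 K).
#' @export
h_effective <- function(env) {
  stopifnot(inherits(env, "bmc_environment"))
  sides <- if (env$convection_sides == "both") 2 else 1
  h <- env$h_conv * sides
  if (env$include_radiation)
    h <- h + 4 * env$emissivity * SIGMA_SB * env$t_ambient^3 * sides
  h
}
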