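#' Characteristic heat-transfer length
#'
#' L_c = volume / heat-transfer area. For a thin beam losing heat through its
#' plan face this is simply the thickness.
#'
#' @param volume Body volume, m^3 (> 0).
#' @param heat_transfer_area Area through which heat is exchanged, m^2 (> 0).
#' @return Characteristic length, m.
#' @export
#' @examples
#' characteristic_length(600e-6 * 76e-6 * 1e-6, 600e-6 * 76e-6)  # 1 um
characteristic_length <- function(volume, heat_transfer_area) {
  check_scalar(volume, "volume", positive = TRUE)
  check_scalar(heat_transfer_area, "heat_transfer_area", positive = TRUE)
  volume / heat_transfer_area
}

#' Biot number and lumped-capacitance validity
#'
#' Bi = h D / k: the ratio of internal conductive resistance to external
#' convective resistance for a body of size `D`. When Bi is far below 1 the
#' internal temperature gradient is negligible and the body may be treated as
#' a lumped mass at a single temperature.
#'
#' @param h Convective heat transfer coefficient, W/(m^2 K) (>= 0).
#' @param size Characteristic body size D, m (> 0).
#' @param conductivity Solid thermal conductivity k, W/(m K) (> 0).
#' @param threshold Validity threshold on Bi; the classical criterion 0.1 by
#'   default.
#' @return The Biot number (numeric scalar) with attributes `lumped_valid`
#'   (logical, Bi < threshold) and `threshold`.
#' @export
#' @examples
#' biot_number(20, 5e-6, 0.03)  # ~0.003 for a 5-um yeast cell
biot_number <- function(h, size, conductivity, threshold = 0.1) {
  check_scalar(h, "h", nonneg = TRUE)
  check_scalar(size, "size", positive = TRUE)
  check_scalar(conductivity, "conductivity", positive = TRUE)
  check_scalar(threshold, "threshold", positive = TRUE)
  bi <- h * size / conductivity
  structure(bi, lumped_valid = bi < threshold, threshold = threshold,
            class = c("bmc_biot", "numeric"))
}

#' @export
print.bmc_biot <- function(x, ...) {
  cat(sprintf("Biot number: %.4g (%s for the lumped approximation, threshold %g)\n",
              unclass(x)[1],
              if (attr(x, "lumped_valid")) "valid" else "NOT valid",
              attr(x, "threshold")))
  invisible(x)
}

#' Beam volume
#'
#' @param geometry A [beam_geometry()].
#' @return length * width * total thickness, m^3.
#' @export
beam_volume <- function(geometry) {
  stopifnot(inherits(geometry, "bmc_geometry"))
  geometry$length * geometry$width * total_thickness(geometry$stack)
}

#' Sample volume
#'
#' @param sample A [sample_spec()].
#' @return The volume override when set, otherwise length * height * width,
#'   m^3.
#' @export
sample_volume <- function(sample) {
  stopifnot(inherits(sample, "bmc_sample"))
  sample$volume_override %||% (sample$length * sample$height * sample$width)
}

#' Beam-to-sample volume ratio
#'
#' V_B / V_S under a configurable convention. `"3d_boxes"` uses the full
#' rectangular volumes; `"2d_extruded"` treats both bodies as cross-sections
#' extruded over a shared width (beam length x total thickness versus sample
#' length x height), matching a two-dimensional model. A `ratio_override`
#' (or, through the model, `volume_ratio_override`) short-circuits both, for
#' prescribed ratios that are not derivable from box dimensions.
#'
#' @param beam A [beam_geometry()].
#' @param sample A [sample_spec()] (its `volume_override` is honoured).
#' @param convention `"3d_boxes"` or `"2d_extruded"`.
#' @param ratio_override Optional prescribed ratio, returned as-is.
#' @param beam_volume_override Optional beam volume, m^3, replacing the
#'   geometric volume.
#' @return Dimensionless ratio V_B / V_S.
#' @export
volume_ratio <- function(beam, sample,
                         convention = c("3d_boxes", "2d_extruded"),
                         ratio_override = NULL,
                         beam_volume_override = NULL) {
  if (!is.null(ratio_override)) {
    check_scalar(ratio_override, "ratio_override", positive = TRUE)
    return(ratio_override)
  }
  stopifnot(inherits(beam, "bmc_geometry"), inherits(sample, "bmc_sample"))
  convention <- match.arg(convention)
  if (convention == "2d_extruded") {
    v_b <- beam$length * total_thickness(beam$stack)
    v_s <- sample$length * sample$height
  } else {
    v_b <- beam_volume_override %||% beam_volume(beam)
    v_s <- sample_volume(sample)
  }
  if (v_s <= 0) stop_domain("sample volume must be > 0")
  v_b / v_s
}

#' Areal heat capacity of a layer stack
#'
#' Heat stored per unit plan area per kelvin: the thickness-weighted sum
#' of rho * Cp over the layers. This is the numerator of the lumped thermal
#' time constant.
#'
#' @param stack A [layer_stack()].
#' @return Areal heat capacity, J/(m^2 K).
#' @export
areal_heat_capacity <- function(stack) {
  stopifnot(inherits(stack, "bmc_stack"))
  volumetric_heat_capacity(stack$top) * stack$t_top +
    volumetric_heat_capacity(stack$bottom) * stack$t_bottom
}
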