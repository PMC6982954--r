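# Shared builders for the default study configuration: a 600 x 76 um
# nitride beam (1 um) with a 500 nm aluminium underlayer, free convection
# h = 20 W/m^2K on both faces, 500 W/m^2 absorbed flux, yeast-like sample.

test_stack <- function(mats = default_materials()) {
  layer_stack(mats$si3n4, mats$aluminium, t_top = 1e-6, t_bottom = 0.5e-6)
}

test_beam <- function() beam_geometry(600e-6, 76e-6, test_stack())

# Model whose geometry is fully self-consistent (no characteristic-length or
# ratio overrides). When `sample_ratio` is given, the sample volume is pinned
# so that V_B / V_S equals it exactly.
test_model <- function(sample_ratio = NULL, h = 20, sides = "both",
                       flux = 500, duration = Inf) {
  geom <- test_beam()
  smp <- NULL
  if (!is.null(sample_ratio)) {
    smp <- sample_spec(default_materials()$yeast, length = 5e-6,
                       height = 2e-6, width = 5e-6,
                       position_on_beam = 300e-6,
                       volume_override = beam_volume(geom) / sample_ratio)
  }
  beam_model(geom,
             environment_spec(h_conv = h, convection_sides = sides),
             irradiation(absorbed_flux = flux, duration = duration),
             sample = smp)
}

# Stack with prescribed thickness ratio m, modulus ratio n and expansion
# difference (bottom minus top); used for curvature identities.
ratio_stack <- function(m, n, d_alpha, t_bottom = 1e-6, e_bottom = 70e9) {
  top <- bmc_material("top", 1000, 1000, 10,
                      thermal_expansion = 0, youngs_modulus = n * e_bottom)
  bottom <- bmc_material("bottom", 1000, 1000, 10,
                         thermal_expansion = d_alpha, youngs_modulus = e_bottom)
  layer_stack(top, bottom, t_top = m * t_bottom, t_bottom = t_bottom)
}

# Noiseless trace evaluated from the step-response formula itself
exp_trace <- function(v_inf, v0, tau, t = seq(0, 0.5, by = 1e-3)) {
  as_deflection_trace(t, v_inf - (v_inf - v0) * exp(-t / tau))
}
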