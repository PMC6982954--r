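#' Write and read deflection-trace CSV files
#'
#' Two columns, `time_s` and `tip_deflection_m`, full double precision
#' (round-trips are lossless to 15 significant digits).
#'
#' @param trace A [as_deflection_trace()] object.
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a `bmc_deflection_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "bmc_deflection_trace"))
  df <- data.frame(time_s = format(trace$times, digits = 17, trim = TRUE,
                                   scientific = TRUE),
                   tip_deflection_m = format(trace$tip, digits = 17,
                                             trim = TRUE, scientific = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, colClasses = "numeric")
  if (!all(c("time_s", "tip_deflection_m") %in% names(df)))
    stop_domain("expected columns `time_s` and `tip_deflection_m`")
  as_deflection_trace(df$time_s, df$tip_deflection_m,
                      meta = list(source = path))
}

#' Write a thermal trace as CSV
#'
#' Lumped traces use columns `time_s,temperature_K`; distributed traces a
#' wide format `time_s,T_node_000,...` with one column per axial node.
#'
#' @param trace A [thermal_trace()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_thermal_csv <- function(trace, path) {
  stopifnot(inherits(trace, "bmc_thermal_trace"))
  if (trace$model == "lumped") {
    df <- data.frame(time_s = trace$times, temperature_K = trace$temperature)
  } else {
    df <- data.frame(time_s = trace$times, trace$temperature)
    names(df)[-1] <- sprintf("T_node_%03d", seq_len(ncol(trace$temperature)) - 1L)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

material_to_list <- function(m) {
  list(name = m$name, density = m$density, specific_heat = m$specific_heat,
       thermal_conductivity = m$thermal_conductivity,
       thermal_expansion = m$thermal_expansion,
       youngs_modulus = m$youngs_modulus)
}

material_from_list <- function(l) {
  bmc_material(l$name, l$density, l$specific_heat, l$thermal_conductivity,
               l$thermal_expansion %||% 0, l$youngs_modulus %||% 1)
}

#' Serialise a beam model to and from a configuration file
#'
#' JSON configuration with sections `beam`, `layers` (`top`, `bottom`),
#' `environment`, `irradiation` and optionally `sample` and `overrides`,
#' all values SI. Numbers are written at full precision, so a write/read
#' round trip reproduces the model exactly.
#'
#' @param model A [beam_model()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `bmc_model`.
#' @export
write_config <- function(model, path) {
  stopifnot(inherits(model, "bmc_model"))
  g <- model$geometry
  cfg <- list(
    beam = list(length = g$length, width = g$width),
    layers = list(
      top = c(material_to_list(g$stack$top), list(thickness = g$stack$t_top)),
      bottom = c(material_to_list(g$stack$bottom),
                 list(thickness = g$stack$t_bottom))),
    environment = list(
      t_ambient = model$environment$t_ambient,
      h_conv = model$environment$h_conv,
      convection_sides = model$environment$convection_sides,
      include_radiation = model$environment$include_radiation,
      emissivity = model$environment$emissivity),
    irradiation = list(
      absorbed_flux = model$irradiation$absorbed_flux,
      t_on = model$irradiation$t_on,
      duration = if (is.finite(model$irradiation$duration))
        model$irradiation$duration else "Inf"))
  if (!is.null(model$sample)) {
    s <- model$sample
    cfg$sample <- list(
      material = material_to_list(s$material),
      length = s$length, height = s$height, width = s$width,
      position_on_beam = s$position_on_beam)
    if (!is.null(s$volume_override)) cfg$sample$volume_override <- s$volume_override
    if (!is.null(s$lc_override)) cfg$sample$lc_override <- s$lc_override
  }
  ov <- list()
  if (!is.null(model$volume_ratio_override))
    ov$volume_ratio <- model$volume_ratio_override
  if (!is.null(model$lc_beam_override))
    ov$lc_beam <- model$lc_beam_override
  if (length(ov)) cfg$overrides <- ov
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  stack <- layer_stack(material_from_list(cfg$layers$top),
                       material_from_list(cfg$layers$bottom),
                       t_top = cfg$layers$top$thickness,
                       t_bottom = cfg$layers$bottom$thickness)
  geom <- beam_geometry(cfg$beam$length, cfg$beam$width, stack)
  env <- environment_spec(cfg$environment$t_ambient, cfg$environment$h_conv,
                          cfg$environment$convection_sides,
                          cfg$environment$include_radiation,
                          cfg$environment$emissivity)
  dur <- cfg$irradiation$duration
  if (identical(dur, "Inf")) dur <- Inf
  irr <- irradiation(cfg$irradiation$absorbed_flux, cfg$irradiation$t_on, dur)
  smp <- NULL
  if (!is.null(cfg$sample)) {
    smp <- sample_spec(material_from_list(cfg$sample$material),
                       cfg$sample$length, cfg$sample$height, cfg$sample$width,
                       cfg$sample$position_on_beam,
                       volume_override = cfg$sample$volume_override,
                       lc_override = cfg$sample$lc_override)
  }
  beam_model(geom, env, irr, sample = smp,
             volume_ratio_override = cfg$overrides$volume_ratio,
             lc_beam_override = cfg$overrides$lc_beam)
}

#' Write and read an exponential fit as JSON
#'
#' Stores the fitted parameters, diagnostics and covariance; enough to feed
#' [estimate_heat_capacity()] after reading back.
#'
#' @param fit A [fit_exponential()] result.
#' @param path File path.
#' @return `write_fit_json()` returns `path` invisibly; `read_fit_json()` a
#'   `bmc_fit` (without the data vectors).
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "bmc_fit"))
  jsonlite::write_json(list(
    v_inf_m = fit$v_inf, v0_m = fit$v0, tau_s = fit$tau,
    rss_m2 = fit$rss, converged = fit$converged,
    covariance = fit$covariance, se = as.list(fit$se),
    sigma_m = fit$sigma, r_squared = fit$r_squared, n = fit$n),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  covm <- matrix(unlist(l$covariance), 3, 3)
  dimnames(covm) <- list(c("v_inf", "v0", "tau"), c("v_inf", "v0", "tau"))
  structure(list(
    v_inf = l$v_inf_m, v0 = l$v0_m, tau = l$tau_s, rss = l$rss_m2,
    converged = isTRUE(l$converged), covariance = covm,
    se = unlist(l$se), sigma = l$sigma_m, r_squared = l$r_squared,
    n = l$n, times = NULL, tip = NULL, fitted = NULL, residuals = NULL,
    message = NULL), class = "bmc_fit")
}

#' Write a heat-capacity estimate as JSON
#'
#' @param est A [estimate_heat_capacity()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(est, path) {
  stopifnot(inherits(est, "bmc_estimate"))
  jsonlite::write_json(
    list(tau_B_s = est$tau_B, tau_T_s = est$tau_T, tau_S_s = est$tau_S,
         lc_B_m = est$lc_B, lc_S_m = est$lc_S, lc_T_m = est$lc_T,
         volume_ratio = est$volume_ratio,
         rho_cp_S_J_per_m3K = est$rho_cp_S,
         se_rho_cp_S_J_per_m3K = est$se_rho_cp_S,
         cp_S_J_per_kgK = est$cp_S, h_eff_W_per_m2K = est$h_eff,
         method = est$method, valid = est$valid, reasons = est$reasons),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
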