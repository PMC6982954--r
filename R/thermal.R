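#' Lumped-capacitance parameters of a beam model
#'
#' Reduces a full [beam_model()] to the first-order energy balance
#' `tc * dT/dt + (T - T_amb) = q_s / h_eff`. The time constant is the areal
#' heat capacity of the stack (plus the sample's heat capacity spread over
#' the beam plan area, when a sample is present) divided by the effective
#' heat-loss coefficient; the steady temperature is `T_amb + q_s / h_eff`.
#'
#' @param model A [beam_model()].
#' @return Object of class `bmc_lumped_params` with fields `tc` (s; `Inf`
#'   when `h_eff` is zero, in which case `no_steady_state` is `TRUE` and
#'   `t_inf` is `NA`), `t_inf` (K), `t0` (K, the ambient start temperature),
#'   `h_eff` (W/(m^2 K)) and `c_areal` (J/(m^2 K)).
#' @export
lumped_params <- function(model) {
  stopifnot(inherits(model, "bmc_model"))
  g <- model$geometry
  h_eff <- h_effective(model$environment)
  c_areal <- areal_heat_capacity(g$stack)
  if (!is.null(model$sample)) {
    c_areal <- c_areal +
      volumetric_heat_capacity(model$sample$material) *
      sample_volume(model$sample) / (g$length * g$width)
  }
  no_steady <- h_eff <= 0
  structure(list(
    tc = if (no_steady) Inf else c_areal / h_eff,
    t_inf = if (no_steady) NA_real_
            else model$environment$t_ambient +
                 model$irradiation$absorbed_flux / h_eff,
    t0 = model$environment$t_ambient,
    h_eff = h_eff, c_areal = c_areal,
    no_steady_state = no_steady),
    class = "bmc_lumped_params")
}

#' @export
print.bmc_lumped_params <- function(x, ...) {
  cat(sprintf("<bmc_lumped_params> tc = %.4g ms, T_inf = %.4g K (rise %.4g K), h_eff = %g W/m^2K\n",
              x$tc * 1e3, x$t_inf, x$t_inf - x$t0, x$h_eff))
  invisible(x)
}

#' Analytic lumped temperature
#'
#' Closed-form solution of the first-order energy balance under constant
#' flux: `T(t) = T_inf + (T0 - T_inf) * exp(-t / tc)`.
#'
#' @param params A [lumped_params()] result (constant-flux parameters).
#' @param t Times, s (>= 0); vectorised.
#' @return Temperatures, K.
#' @export
lumped_temperature <- function(params, t) {
  stopifnot(inherits(params, "bmc_lumped_params"))
  if (any(t < 0)) stop_domain("`t` must be >= 0")
  if (params$no_steady_state)
    stop_domain("h_eff = 0: no steady state exists; use simulate_lumped_ode()")
  params$t_inf + (params$t0 - params$t_inf) * exp(-t / params$tc)
}

flux_at <- function(irr, t) {
  ifelse(t >= irr$t_on & t < irr$t_on + irr$duration, irr$absorbed_flux, 0)
}

# Breakpoints of the piecewise-constant flux inside [t0, t1]
flux_breakpoints <- function(irr, t0, t1) {
  b <- c(irr$t_on, irr$t_on + irr$duration)
  sort(unique(b[is.finite(b) & b > t0 & b < t1]))
}

#' A thermal trace
#'
#' Container for simulated temperatures: a vector (lumped model) or a
#' time-by-node matrix (distributed model) on a strictly increasing time
#' grid.
#'
#' @param times Time grid, s, strictly increasing.
#' @param temperature Numeric vector (lumped) or matrix with
#'   `length(times)` rows (distributed), K, all finite.
#' @param model `"lumped"` or `"distributed"`.
#' @param x Node positions for a distributed trace, m.
#' @param t_ambient Ambient temperature, K.
#' @return Object of class `bmc_thermal_trace`.
#' @export
thermal_trace <- function(times, temperature, model = c("lumped", "distributed"),
                          x = NULL, t_ambient = NA_real_) {
  model <- match.arg(model)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop_domain("`times` must be strictly increasing with >= 2 points")
  if (!all(is.finite(temperature)))
    stop_domain("temperatures must be finite")
  if (model == "lumped") {
    if (length(temperature) != length(times))
      stop_domain("lumped trace: temperature length must match times")
  } else {
    temperature <- as.matrix(temperature)
    if (nrow(temperature) != length(times))
      stop_domain("distributed trace: one temperature row per time point")
    if (is.null(x) || length(x) != ncol(temperature))
      stop_domain("distributed trace: `x` must give one position per node")
  }
  structure(list(times = times, temperature = temperature, model = model,
                 x = x, t_ambient = t_ambient),
            class = "bmc_thermal_trace")
}

#' Simulate the lumped energy balance
#'
#' Integrates `C_A dT/dt = q_s(t) - h_eff (T - T_amb)` on the given grid.
#' The flux may switch on and off ([irradiation()]); integration is split at
#' the flux discontinuities. `method = "lsoda"` (default) uses a genuine
#' adaptive ODE integrator at tight tolerance, so that agreement with the
#' analytic solution is a meaningful cross-check; `method = "exponential"`
#' uses the exact exponential step for the piecewise-constant linear ODE and
#' is what the synthetic generator calls.
#'
#' @param model A [beam_model()].
#' @param times Strictly increasing time grid, s.
#' @param method `"lsoda"` or `"exponential"`.
#' @return A lumped [thermal_trace()].
#' @export
simulate_lumped_ode <- function(model, times, method = c("lsoda", "exponential")) {
  stopifnot(inherits(model, "bmc_model"))
  method <- match.arg(method)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop_domain("`times` must be strictly increasing")
  p <- lumped_params(model)
  env <- model$environment
  irr <- model$irradiation
  t0 <- times[1]
  breaks <- flux_breakpoints(irr, t0, times[length(times)])
  seg_edges <- c(t0, breaks, times[length(times)])
  temp <- numeric(length(times))
  state <- env$t_ambient
  for (i in seq_len(length(seg_edges) - 1L)) {
    a <- seg_edges[i]; b <- seg_edges[i + 1L]
    q <- flux_at(irr, a)
    inside <- times > a & times <= b
    grid <- unique(c(a, times[inside], b))
    if (method == "exponential") {
      vals <- exact_segment(state, grid - a, q, p, env$t_ambient)
    } else {
      sol <- deSolve::ode(
        y = c(T = state), times = grid,
        func = function(t, y, parms) {
          list((q - p$h_eff * (y[1] - env$t_ambient)) / p$c_areal)
        },
        method = "lsoda", rtol = 1e-12, atol = 1e-12)
      vals <- sol[, 2]
    }
    if (any(inside)) temp[inside] <- vals[match(times[inside], grid)]
    state <- vals[length(vals)]
  }
  temp[times == t0] <- env$t_ambient
  thermal_trace(times, temp, "lumped", t_ambient = env$t_ambient)
}

# exact solution over one constant-flux segment, tau relative times
exact_segment <- function(T_start, tau, q, p, t_amb) {
  if (p$h_eff <= 0) {
    # pure heating, no loss: linear ramp
    return(T_start + q * tau / p$c_areal)
  }
  t_inf <- t_amb + q / p$h_eff
  tc <- p$c_areal / p$h_eff
  t_inf + (T_start - t_inf) * exp(-tau / tc)
}

#' Simulate a one-dimensional distributed thermal model
#'
#' A fin-type conduction-convection model along the beam axis:
#' `C_A(x) dT/dt = P d2T/dx2 + q_s(t) - h_eff (T - T_amb)`, where
#' `P = sum(k_i t_i)` is the axial conductance-thickness product of the stack
#' and `C_A(x)` the areal heat capacity (augmented over the sample footprint
#' when a sample is present). Solved by Crank-Nicolson on a uniform node grid
#' with a configurable anchor boundary condition (default adiabatic, matching
#' the lumped treatment which has no base conduction loss) and an adiabatic
#' free tip. Crank-Nicolson is unconditionally stable; `substeps` refines the
#' time step below the output grid for accuracy.
#'
#' @param model A [beam_model()].
#' @param times Strictly increasing output time grid, s.
#' @param n_nodes Number of axial nodes (>= 3), default 200.
#' @param anchor `"adiabatic"` or `"fixed"` (anchor clamped at T_ambient).
#' @param substeps Integer >= 1: internal time steps per output interval.
#' @param conductance_scale Multiplier on the axial conductance `P`, for
#'   exploring the low- and high-conductivity limits.
#' @return A distributed [thermal_trace()].
#' @export
simulate_distributed_1d <- function(model, times, n_nodes = 200,
                                    anchor = c("adiabatic", "fixed"),
                                    substeps = 1, conductance_scale = 1) {
  stopifnot(inherits(model, "bmc_model"))
  anchor <- match.arg(anchor)
  if (n_nodes < 3) stop_domain("`n_nodes` must be >= 3")
  if (length(times) < 2L || any(diff(times) <= 0))
    stop_domain("`times` must be strictly increasing")
  substeps <- max(1L, as.integer(substeps))
  g <- model$geometry
  env <- model$environment
  irr <- model$irradiation
  stack <- g$stack
  h_eff <- h_effective(env)
  P <- (stack$top$thermal_conductivity * stack$t_top +
        stack$bottom$thermal_conductivity * stack$t_bottom) * conductance_scale
  x <- seq(0, g$length, length.out = n_nodes)
  dx <- x[2] - x[1]
  c_areal <- rep(areal_heat_capacity(stack), n_nodes)
  if (!is.null(model$sample)) {
    s <- model$sample
    half <- s$length / 2
    foot <- x >= (s$position_on_beam - half) & x <= (s$position_on_beam + half)
    if (!any(foot)) foot[which.min(abs(x - s$position_on_beam))] <- TRUE
    add <- volumetric_heat_capacity(s$material) * sample_volume(s) /
      (sum(foot) * dx * g$width)
    c_areal[foot] <- c_areal[foot] + add
  }
  r <- P / dx^2
  n_t <- length(times)
  temp <- matrix(env$t_ambient, n_t, n_nodes)
  Tn <- rep(env$t_ambient, n_nodes)
  for (i in seq_len(n_t - 1L)) {
    dt_out <- times[i + 1L] - times[i]
    dt <- dt_out / substeps
    for (s_i in seq_len(substeps)) {
      t_a <- times[i] + (s_i - 1L) * dt
      # flux treated Crank-Nicolson-wise at the two sub-step endpoints
      q_a <- flux_at(irr, t_a)
      q_b <- flux_at(irr, t_a + dt)
      Tn <- cn_step(Tn, dt, r, h_eff, c_areal, q_a, q_b, env$t_ambient, anchor)
    }
    temp[i + 1L, ] <- Tn
  }
  thermal_trace(times, temp, "distributed", x = x, t_ambient = env$t_ambient)
}

# One Crank-Nicolson step of the semi-discrete fin equation.
# Interior: (C/dt + r + h/2) T1_j - (r/2)(T1_{j-1} + T1_{j+1})
#         = (C/dt - r - h/2) T0_j + (r/2)(T0_{j-1} + T0_{j+1}) + qbar + h Tamb
# Neumann ends use the mirrored ghost node (factor 2 on the single neighbour).
cn_step <- function(T0, dt, r, h, c_areal, q_a, q_b, t_amb, anchor) {
  n <- length(T0)
  qbar <- (q_a + q_b) / 2
  a <- c_areal / dt
  dl <- rep(-r / 2, n - 1L)
  du <- rep(-r / 2, n - 1L)
  dg <- a + r + h / 2
  # adiabatic ends: mirror ghost -> the single off-diagonal carries weight r
  du[1] <- -r; dl[n - 1L] <- -r
  rhs <- numeric(n)
  lap0 <- c(2 * (T0[2] - T0[1]),
            T0[-c(1, 2)] - 2 * T0[-c(1, n)] + T0[-c(n - 1L, n)],
            2 * (T0[n - 1L] - T0[n]))
  rhs <- (a - h / 2) * T0 + (r / 2) * lap0 + qbar + h * t_amb
  if (anchor == "fixed") {
    dg[1] <- 1; du[1] <- 0; rhs[1] <- t_amb
  }
  thomas_solve(dl, dg, du, rhs)
}

# Thomas algorithm for a tridiagonal system
thomas_solve <- function(dl, dg, du, rhs) {
  n <- length(dg)
  cp <- numeric(n - 1L); dp <- numeric(n)
  cp[1] <- du[1] / dg[1]
  dp[1] <- rhs[1] / dg[1]
  for (i in 2:n) {
    m <- dg[i] - dl[i - 1L] * cp[i - 1L]
    if (i < n) cp[i] <- du[i] / m
    dp[i] <- (rhs[i] - dl[i - 1L] * dp[i - 1L]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

#' Spatial uniformity of a distributed trace
#'
#' The largest instantaneous spatial temperature spread, normalised by the
#' overall mean temperature rise: `max_t (max_x T - min_x T) / max_t
#' (mean_x T - T_start)`. A small value certifies that the beam behaves as a
#' lumped mass. Zero is returned for an identically uniform trace (including
#' the unheated case, where the rise is zero).
#'
#' @param trace A distributed [thermal_trace()].
#' @return Dimensionless uniformity metric (0 = perfectly uniform).
#' @export
spatial_uniformity <- function(trace) {
  stopifnot(inherits(trace, "bmc_thermal_trace"))
  if (trace$model != "distributed")
    stop_domain("spatial_uniformity() needs a distributed trace")
  temp <- trace$temperature
  spread <- apply(temp, 1L, function(row) max(row) - min(row))
  if (max(spread) == 0) return(0)
  base <- mean(temp[1L, ])
  rise <- max(rowMeans(temp)) - base
  if (rise <= 0) return(Inf)
  max(spread) / rise
}
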