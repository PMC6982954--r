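#' Construct a tip-deflection trace
#'
#' The instrument observable: tip displacement sampled on a strictly
#' increasing time grid. At least four points are required (three model
#' parameters plus one residual degree of freedom).
#'
#' @param times Times, s, strictly increasing.
#' @param tip Tip displacement, m, finite.
#' @param meta Free-form provenance list (seed, configuration, noise level).
#' @return Object of class `bmc_deflection_trace`.
#' @export
as_deflection_trace <- function(times, tip, meta = list()) {
  if (length(times) < 4L)
    stop_domain("a deflection trace needs >= 4 points")
  if (any(diff(times) <= 0))
    stop_domain("`times` must be strictly increasing")
  if (length(tip) != length(times) || !all(is.finite(tip)))
    stop_domain("`tip` must be finite and match `times` in length")
  structure(list(times = as.numeric(times), tip = as.numeric(tip),
                 meta = meta),
            class = "bmc_deflection_trace")
}

#' @export
print.bmc_deflection_trace <- function(x, ...) {
  cat(sprintf("<bmc_deflection_trace> %d points over %.4g s, tip range [%.4g, %.4g] um\n",
              length(x$times), diff(range(x$times)),
              min(x$tip) * 1e6, max(x$tip) * 1e6))
  invisible(x)
}

#' Starting values for the exponential fit
#'
#' Plateau from the mean of the last decile of points, offset from the first
#' point, and time constant from the first e-folding crossing (linear
#' interpolation); falls back to a third of the record length when the trace
#' never crosses the e-folding level (e.g. a linear ramp).
#'
#' @param trace A [as_deflection_trace()] object.
#' @return Named list `v_inf`, `v0`, `tau`.
#' @export
initial_guess <- function(trace) {
  stopifnot(inherits(trace, "bmc_deflection_trace"))
  tip <- trace$tip; times <- trace$times
  n <- length(tip)
  rng <- diff(range(tip))
  if (rng <= 1e-10 * max(abs(tip), 1e-300))
    stop_domain("degenerate (flat) trace: exponential fit is unidentifiable")
  v_inf <- mean(tip[seq.int(max(1L, n - ceiling(0.1 * n) + 1L), n)])
  v0 <- tip[1]
  if (abs(v_inf - v0) < 1e-9 * rng)
    stop_domain("degenerate trace: initial and plateau levels coincide")
  target <- v0 + (1 - exp(-1)) * (v_inf - v0)
  s <- sign(v_inf - v0)
  crossed <- which(s * (tip - target) >= 0)
  crossed <- crossed[crossed > 1L]
  if (length(crossed)) {
    j <- crossed[1]
    f <- (target - tip[j - 1L]) / (tip[j] - tip[j - 1L])
    tau <- times[j - 1L] + f * (times[j] - times[j - 1L]) - times[1]
  } else {
    tau <- diff(range(times)) / 3
  }
  if (!is.finite(tau) || tau <= 0) tau <- diff(range(times)) / 3
  list(v_inf = v_inf, v0 = v0, tau = tau)
}

exp_model <- function(p, t) p[1] - (p[1] - p[2]) * exp(-t / p[3])

# Jacobian of the model values w.r.t. (v_inf, v0, tau)
exp_jacobian <- function(p, t) {
  E <- exp(-t / p[3])
  cbind(v_inf = 1 - E, v0 = E, tau = -(p[1] - p[2]) * E * t / p[3]^2)
}

#' Three-parameter exponential fit of a deflection trace
#'
#' Unweighted nonlinear least squares of
#' `v(t) = v_inf - (v_inf - v0) * exp(-(t - t_start) / tau)`
#' (the first-order step response in the plateau/offset/time-constant
#' parameterisation), by Levenberg-Marquardt with an analytic Jacobian,
#' started from [initial_guess()] values and constrained to `tau > 0`.
#' The parameter covariance is `sigma^2 (J'J)^{-1}` from the Jacobian at the
#' solution. Non-convergence is reported through the `converged` flag rather
#' than an error; a flat trace raises an error.
#'
#' Times are shifted so the first sample is the fit origin; `tau` is
#' unaffected by such shifts.
#'
#' @param trace A [as_deflection_trace()] object.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return Object of class `bmc_fit`: `v_inf`, `v0` (m), `tau` (s), `rss`
#'   (m^2), `converged`, `covariance` (3x3, parameter units squared), `se`
#'   (named standard errors), `sigma` (residual sd, m), `r_squared`, `n`,
#'   and the data (`times`, `tip`, `fitted`, `residuals`).
#' @export
fit_exponential <- function(trace, maxiter = 500) {
  stopifnot(inherits(trace, "bmc_deflection_trace"))
  g <- initial_guess(trace)
  t_rel <- trace$times - trace$times[1]
  v <- trace$tip
  lm <- minpack.lm::nls.lm(
    par = c(v_inf = g$v_inf, v0 = g$v0, tau = g$tau),
    lower = c(-Inf, -Inf, .Machine$double.xmin),
    fn = function(p) v - exp_model(p, t_rel),
    jac = function(p) -exp_jacobian(p, t_rel),
    control = minpack.lm::nls.lm.control(
      maxiter = maxiter, ftol = 1e-15, ptol = 1e-15, gtol = 0))
  p <- lm$par
  fitted <- exp_model(p, t_rel)
  res <- v - fitted
  rss <- sum(res^2)
  n <- length(v)
  sigma <- sqrt(rss / max(1L, n - 3L))
  J <- exp_jacobian(p, t_rel)
  covm <- tryCatch(sigma^2 * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, 3, 3))
  dimnames(covm) <- list(names(p), names(p))
  tss <- sum((v - mean(v))^2)
  structure(list(
    v_inf = unname(p["v_inf"]), v0 = unname(p["v0"]), tau = unname(p["tau"]),
    rss = rss,
    converged = lm$info %in% 1:4 && p["tau"] > 0,
    covariance = covm, se = sqrt(pmax(diag(covm), 0)),
    sigma = sigma,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n = n,
    times = trace$times, tip = trace$tip,
    fitted = fitted, residuals = as.numeric(res),
    message = lm$message), class = "bmc_fit")
}

#' @export
print.bmc_fit <- function(x, ...) {
  if (!x$converged) cat("<bmc_fit> NOT converged\n")
  cat(sprintf("<bmc_fit> v_inf = %.6g um, v0 = %.6g um, tau = %.6g ms (n = %d)\n",
              x$v_inf * 1e6, x$v0 * 1e6, x$tau * 1e3, x$n))
  if (is.finite(x$r_squared))
    cat(sprintf("  rss = %.4g m^2, R^2 = %.8g\n", x$rss, x$r_squared))
  invisible(x)
}

#' Human-readable fit summary with residual series
#'
#' @param fit A [fit_exponential()] result.
#' @param trace The fitted trace (used only for provenance echoing).
#' @return Object of class `bmc_fit_report` with a `summary` character
#'   vector (reporting in the instrument's customary micrometres and
#'   milliseconds) and a `residuals` data frame (`time_s`, `residual_m`).
#' @export
fit_report <- function(fit, trace = NULL) {
  stopifnot(inherits(fit, "bmc_fit"))
  lines <- c(
    "Exponential step-response fit: v(t) = v_inf - (v_inf - v0) exp(-t/tau)",
    sprintf("  v_inf = %.6g um (se %.3g um)", fit$v_inf * 1e6, fit$se[["v_inf"]] * 1e6),
    sprintf("  v0    = %.6g um (se %.3g um)", fit$v0 * 1e6, fit$se[["v0"]] * 1e6),
    sprintf("  tau   = %.6g ms (se %.3g ms)", fit$tau * 1e3, fit$se[["tau"]] * 1e3),
    sprintf("  n = %d, rss = %.6g m^2, residual sd = %.4g um, R^2 = %.8g",
            fit$n, fit$rss, fit$sigma * 1e6, fit$r_squared),
    sprintf("  converged: %s", fit$converged))
  if (!is.null(trace) && length(trace$meta))
    lines <- c(lines, sprintf("  trace meta: %s",
                              paste(names(trace$meta),
                                    vapply(trace$meta, function(v)
                                      paste(format(v), collapse = ","),
                                      character(1)),
                                    sep = "=", collapse = "; ")))
  structure(list(summary = lines,
                 residuals = data.frame(time_s = fit$times,
                                        residual_m = fit$residuals),
                 r_squared = fit$r_squared),
            class = "bmc_fit_report")
}

#' @export
print.bmc_fit_report <- function(x, ...) {
  cat(x$summary, sep = "\n")
  invisible(x)
}
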