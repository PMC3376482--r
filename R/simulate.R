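#' Driving-pressure waveform
#'
#' Wraps a pressure function of time with its phase domain; evaluation
#' outside the domain is an error.
#'
#' @param f function `t -> pressure` (cmH2O), vectorised.
#' @param t_start,t_end phase domain (s).
#' @param label descriptive label.
#' @return an object of class `pressure_waveform`, callable as a function.
#' @export
pressure_waveform <- function(f, t_start, t_end, label = "pressure") {
  stopifnot(is.function(f), t_end > t_start)
  g <- function(t) {
    # small slack for integrators that step marginally past the interval end
    slack <- 0.01 * (t_end - t_start)
    if (any(t < t_start - slack) || any(t > t_end + slack))
      stop("pressure waveform '", label, "' evaluated outside its domain [",
           t_start, ", ", t_end, "]")
    p <- f(pmin(pmax(t, t_start), t_end))
    if (any(!is.finite(p))) stop("pressure waveform '", label, "' is not finite")
    p
  }
  structure(g, class = c("pressure_waveform", "function"),
            t_start = t_start, t_end = t_end, label = label)
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("<pressure_waveform> '%s' on [%g, %g] s\n",
              attr(x, "label"), attr(x, "t_start"), attr(x, "t_end")))
  invisible(x)
}

#' Nonoptimal reference pressure waveforms
#'
#' The reference (nonoptimal) ventilation pattern used for comparison: a
#' linearly increasing inspiratory pressure `p_in(t) = 20 t + 5` cmH2O on
#' `[0, T_in]` and passive expiration at atmospheric (gauge zero) pressure on
#' `[T_in, T_in + T_ex]`.
#'
#' @param T_in,T_ex phase durations (s).
#' @return list with elements `inspiration` and `expiration`, both
#'   [pressure_waveform()]s.
#' @export
reference_pressures <- function(T_in, T_ex) {
  stopifnot(T_in > 0, T_ex > 0)
  list(
    inspiration = pressure_waveform(function(t) 20 * t + 5, 0, T_in,
                                    label = "linear ramp 20t + 5"),
    expiration = pressure_waveform(function(t) rep(0, length(t)), T_in,
                                   T_in + T_ex, label = "passive (0 cmH2O)"))
}

#' Forward-simulate one breathing phase
#'
#' Integrates the compartmental pressure-balance dynamics
#' `xdot = R^{-1} (p(t) e - C(x) x)` under an applied pressure waveform,
#' using smoothed compliance. Flows are recovered exactly from the state
#' equation and accelerations analytically by differentiating it (using the
#' analytic derivative of reciprocal compliance), avoiding numerical
#' differentiation noise.
#'
#' @param model a [lung_model()].
#' @param phase `"inspiration"` or `"expiration"`.
#' @param pressure a [pressure_waveform()] (or plain function of time).
#' @param x0 initial volume vector (l), nonnegative.
#' @param t_span time interval `c(t0, t1)` (s); defaults to the waveform
#'   domain.
#' @param n_grid number of output nodes (odd recommended for Simpson
#'   quadrature downstream).
#' @param rtol,atol integrator tolerances.
#' @return a [new_trajectory()] object.
#' @examples
#' fx <- lung_fixture("two_compartment")
#' pr <- reference_pressures(2, 3)
#' traj <- simulate_phase(fx$model, "inspiration", pr$inspiration,
#'                        x0 = fx$spec$V0)
#' glance(traj)
#' @export
simulate_phase <- function(model, phase = c("inspiration", "expiration"),
                           pressure, x0, t_span = NULL, n_grid = 401L,
                           rtol = 1e-8, atol = 1e-10) {
  phase <- match.arg(phase)
  if (is.null(t_span)) {
    t_span <- c(attr(pressure, "t_start") %||% 0,
                attr(pressure, "t_end") %||% 1)
  }
  stopifnot(length(x0) == model$m, all(x0 >= 0), diff(t_span) > 0)
  R <- phase_R(model, phase)
  Rinv <- solve(R)
  times <- seq(t_span[1], t_span[2], length.out = n_grid)
  deriv <- function(t, x, parms) {
    list(drop(Rinv %*% (pressure(t) - inv_compliance_vec(model, pmax(x, 0), phase) * x)))
  }
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("simulate_phase: integration failed at t = ", max(sol[, 1]),
         " (last valid state ", paste(signif(sol[nrow(sol), -1], 6), collapse = ", "), ")")
  x <- unname(sol[, -1, drop = FALSE])
  p <- pressure(times)
  # flows from the state equation; accelerations from its time derivative:
  # R xddot = pdot e - C(x) xdot - C'(x) diag(xdot) x
  u <- t(matrix(vapply(seq_len(n_grid), function(k)
    inv_compliance_vec(model, pmax(x[k, ], 0), phase), numeric(model$m)),
    nrow = model$m))
  du <- t(matrix(vapply(seq_len(n_grid), function(k)
    inv_compliance_deriv_vec(model, pmax(x[k, ], 0), phase), numeric(model$m)),
    nrow = model$m))
  dx <- (p - u * x) %*% Rinv
  hp <- diff(t_span) * 1e-7
  pdot <- vapply(times, function(t) {
    tl <- max(t - hp, t_span[1]); tr <- min(t + hp, t_span[2])
    (pressure(tr) - pressure(tl)) / (tr - tl)
  }, numeric(1))
  ddx <- (pdot - u * dx - du * dx * x) %*% Rinv
  new_trajectory(times, x, dx, ddx, phase)
}
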