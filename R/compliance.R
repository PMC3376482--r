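#' Volume-dependent compartment compliance
#'
#' A lung compartment's compliance (volume per unit distending pressure,
#' l/cmH2O) is modelled as a three-segment piecewise-linear function of
#' compartment volume: a rising segment `a1 + b1*x` at low volume, a constant
#' plateau `a2` between the breakpoints `x1` and `x2`, and a falling segment
#' `a3 + b3*x` at high volume. For use inside differential equations the
#' piecewise curve is replaced by a smooth sigmoid-difference approximation
#' `a2 * (S[a,b](x) - S[c,d](x))` whose sharpness is controlled by
#' `beta_smooth`; the anchors are `a = -a1/b1`, `b = a2/b1 + a`,
#' `c = -a3/b3`, `d = a2/b3 + c`.
#'
#' @param a1,a2,a3 segment intercepts (l/cmH2O); `a2` is the plateau value.
#' @param b1 rising-segment slope, must be positive ((l/cmH2O)/l).
#' @param b3 falling-segment slope, must be negative ((l/cmH2O)/l).
#' @param x1,x2 breakpoint volumes (l), `0 < x1 < x2`.
#' @param v_cap upper volume of the stated domain (l); the falling segment is
#'   extended affinely beyond it.
#' @param beta_smooth sigmoid sharpness (1/l); larger is closer to the
#'   piecewise curve.
#' @param phase `"inspiration"` or `"expiration"`, a label only.
#' @return an object of class `compliance_curve`.
#' @examples
#' cc <- compliance_curve(a1 = 0.018, b1 = 0.0233, a2 = 0.025,
#'                        a3 = 0.2532, b3 = -0.01, x1 = 0.3, x2 = 0.48,
#'                        v_cap = 0.6, phase = "inspiration")
#' compliance_value(cc, 0.4)
#' @export
compliance_curve <- function(a1, b1, a2, a3, b3, x1, x2, v_cap,
                             beta_smooth = 30,
                             phase = c("inspiration", "expiration")) {
  phase <- match.arg(phase)
  stopifnot(is.numeric(a1), is.numeric(a2), is.numeric(a3))
  if (!(b1 > 0)) stop("compliance_curve: b1 must be > 0, got ", b1)
  if (!(b3 < 0)) stop("compliance_curve: b3 must be < 0, got ", b3)
  if (!(0 < x1 && x1 < x2 && x2 <= v_cap))
    stop("compliance_curve: need 0 < x1 < x2 <= v_cap, got x1=", x1,
         ", x2=", x2, ", v_cap=", v_cap)
  if (!(beta_smooth > 0)) stop("compliance_curve: beta_smooth must be > 0")
  # sigmoid anchors of the smooth form
  a <- -a1 / b1; b <- a2 / b1 + a
  c <- -a3 / b3; d <- a2 / b3 + c
  if (!all(is.finite(c(a, b, c, d))) || !(a < b) || !(d < c))
    stop("compliance_curve: degenerate sigmoid anchors (need a < b and d < c)")
  # the printed parameter sets need not make the curve continuous at x2
  seg3_at_x2 <- a3 + b3 * x2
  if (abs(seg3_at_x2 - a2) > 0.01 * abs(a2))
    warning(sprintf(paste0("compliance_curve (%s): piecewise curve is ",
                           "discontinuous at x2 = %g (segment 3 gives %.4g, ",
                           "plateau is %.4g)"), phase, x2, seg3_at_x2, a2),
            call. = FALSE)
  structure(
    list(a1 = a1, b1 = b1, a2 = a2, a3 = a3, b3 = b3,
         x1 = x1, x2 = x2, v_cap = v_cap, beta_smooth = beta_smooth,
         phase = phase, anchors = c(a = a, b = b, c = c, d = d)),
    class = "compliance_curve")
}

#' @export
print.compliance_curve <- function(x, ...) {
  cat(sprintf("<compliance_curve [%s]> plateau %.4g l/cmH2O on [%.3g, %.3g] l, beta = %g\n",
              x$phase, x$a2, x$x1, x$x2, x$beta_smooth))
  invisible(x)
}

# smooth ramp S_{a,b}(x): 0 below a, linear between, 1 above (beta -> Inf)
sigmoid_step <- function(x, a, b, beta) {
  (softplus(beta * (x - a)) - softplus(beta * (x - b))) / (beta * (b - a))
}

sigmoid_step_deriv <- function(x, a, b, beta) {
  (plogis(beta * (x - a)) - plogis(beta * (x - b))) / (b - a)
}

# floor keeping 1/c finite when the smooth curve decays towards zero
.C_FLOOR <- 1e-6

#' Evaluate a compliance curve
#'
#' Piecewise mode uses left-closed segments (`[0, x1]`, `(x1, x2]`,
#' `(x2, Inf)`) with the third segment extended affinely above `v_cap`.
#' Smoothed mode evaluates the sigmoid-difference approximation, defined for
#' all nonnegative volumes. Both modes floor the result at `1e-6` l/cmH2O so
#' the reciprocal stays finite.
#'
#' @param curve a [compliance_curve()].
#' @param x volume (l), vectorised; must be nonnegative.
#' @param mode `"smoothed"` (default, used inside all solvers) or
#'   `"piecewise"`.
#' @return compliance values (l/cmH2O), same length as `x`.
#' @export
compliance_value <- function(curve, x, mode = c("smoothed", "piecewise")) {
  mode <- match.arg(mode)
  if (any(x < 0)) stop("compliance_value: volume must be nonnegative")
  val <- if (mode == "piecewise") {
    ifelse(x <= curve$x1, curve$a1 + curve$b1 * x,
           ifelse(x <= curve$x2, curve$a2, curve$a3 + curve$b3 * x))
  } else {
    an <- curve$anchors
    curve$a2 * (sigmoid_step(x, an["a"], an["b"], curve$beta_smooth) -
                  sigmoid_step(x, an["c"], an["d"], curve$beta_smooth))
  }
  unname(pmax(val, .C_FLOOR))
}

#' Derivative of reciprocal compliance
#'
#' Analytic `d/dx (1/c(x))` of the smoothed compliance form (the piecewise
#' reciprocal is not differentiable at the breakpoints), the quantity entering
#' the expiratory Euler-Lagrange equation through `C_ex'(x)`.
#'
#' @inheritParams compliance_value
#' @return derivative values (cmH2O/l^2), same length as `x`.
#' @export
inv_compliance_derivative <- function(curve, x) {
  if (any(x < 0)) stop("inv_compliance_derivative: volume must be nonnegative")
  an <- curve$anchors
  cval <- curve$a2 * (sigmoid_step(x, an["a"], an["b"], curve$beta_smooth) -
                        sigmoid_step(x, an["c"], an["d"], curve$beta_smooth))
  dc <- curve$a2 * (sigmoid_step_deriv(x, an["a"], an["b"], curve$beta_smooth) -
                      sigmoid_step_deriv(x, an["c"], an["d"], curve$beta_smooth))
  # below the floor the working compliance is constant, so the derivative is 0
  unname(ifelse(cval <= .C_FLOOR, 0, -dc / cval^2))
}
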