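#' Optimal inspiratory volume trajectory (closed form)
#'
#' Minimizes the inspiratory criterion
#' `J_in(x) = int_0^T_in [ xddot' xddot + alpha1 * p_in(t) e' xdot ] dt`
#' subject to `x(0) = V0`, `xdot(0) = 0`, `x(T_in) = V0 + VT`,
#' `xdot(T_in) = 0`. After eliminating the pressure through the state
#' equation, the Euler-Lagrange equation is the linear fourth-order system
#' `x'''' - alpha1 R_in x'' = 0`, whose solution is
#' `x(t) = d1 + d2 t + exp(A t) d3 + exp(-A t) d4` with
#' `A = sqrt(alpha1) R_in^{1/2}` (unique symmetric positive-definite square
#' root) for `alpha1 > 0`, and the cubic
#' `d1 + d2 t + d3 t^2 + d4 t^3` with `d1 = V0`, `d2 = 0`,
#' `d3 = 3 VT / T_in^2`, `d4 = -2 VT / T_in^3` for `alpha1 = 0`. The optimal
#' inspiratory pattern does not depend on the compliance.
#'
#' The boundary system is solved mode-by-mode in the eigenbasis of `R_in`
#' with a centered cosh/sinh parametrization, so no large exponentials are
#' formed.
#'
#' @param model a [lung_model()].
#' @param spec a [breath_spec()].
#' @param n_grid number of output nodes (default 401).
#' @return a [new_trajectory()] with attribute `coefficients`, an object of
#'   class `closed_form_coefficients` (vectors `d1..d4`, matrix `A`, branch
#'   tag).
#' @examples
#' fx <- lung_fixture("two_compartment")
#' traj <- solve_inspiration(fx$model, fx$spec)
#' glance(traj)
#' @export
solve_inspiration <- function(model, spec, n_grid = 401L) {
  check_model_spec(model, spec)
  T_in <- spec$T_in; a1 <- spec$alpha1
  m <- model$m
  times <- seq(0, T_in, length.out = n_grid)
  if (a1 == 0) {
    d1 <- spec$V0; d2 <- rep(0, m)
    d3 <- 3 * spec$VT / T_in^2; d4 <- -2 * spec$VT / T_in^3
    x   <- outer(rep(1, n_grid), d1) + outer(times, d2) +
           outer(times^2, d3) + outer(times^3, d4)
    dx  <- outer(rep(1, n_grid), d2) + outer(2 * times, d3) +
           outer(3 * times^2, d4)
    ddx <- outer(2 * rep(1, n_grid), d3) + outer(6 * times, d4)
    d3x <- outer(6 * rep(1, n_grid), d4)
    coef <- structure(list(d1 = d1, d2 = d2, d3 = d3, d4 = d4, A = NULL,
                           branch = "cubic", T_in = T_in),
                      class = "closed_form_coefficients")
    interp <- function(t) list(
      x = outer(rep(1, length(t)), d1) + outer(t, d2) +
        outer(t^2, d3) + outer(t^3, d4),
      dx = outer(rep(1, length(t)), d2) + outer(2 * t, d3) + outer(3 * t^2, d4),
      ddx = outer(2 * rep(1, length(t)), d3) + outer(6 * t, d4),
      d3x = outer(6 * rep(1, length(t)), d4))
  } else {
    eg <- eigen((model$R_in + t(model$R_in)) / 2, symmetric = TRUE)
    Q <- eg$vectors
    mu <- sqrt(a1) * sqrt(eg$values)   # modal rates of exp(+-A t)
    v0 <- drop(crossprod(Q, spec$V0))
    vT <- drop(crossprod(Q, spec$VT))
    mid <- T_in / 2
    # per mode: x(t) = d1 + d2 t + p cosh(mu (t - mid)) + q sinh(mu (t - mid))
    sol <- vapply(seq_len(m), function(i) {
      mu_i <- mu[i]
      ch <- cosh(mu_i * mid); sh <- sinh(mu_i * mid)
      M <- rbind(
        c(1, 0,       ch,          -sh),          # x(0) = v0
        c(0, 1, -mu_i * sh,  mu_i * ch),          # xdot(0) = 0
        c(1, T_in,    ch,           sh),          # x(T) = v0 + vT
        c(0, 1,  mu_i * sh,  mu_i * ch))          # xdot(T) = 0
      drop(solve(M, c(v0[i], 0, v0[i] + vT[i], 0)))
    }, numeric(4))
    d1m <- sol[1, ]; d2m <- sol[2, ]; pm <- sol[3, ]; qm <- sol[4, ]
    eval_modes <- function(t) {
      tt <- t - mid
      ch <- outer(tt, mu, function(s, u) cosh(u * s))
      sh <- outer(tt, mu, function(s, u) sinh(u * s))
      xm   <- outer(rep(1, length(t)), d1m) + outer(t, d2m) +
              sweep(ch, 2, pm, `*`) + sweep(sh, 2, qm, `*`)
      dxm  <- outer(rep(1, length(t)), d2m) +
              sweep(sh, 2, pm * mu, `*`) + sweep(ch, 2, qm * mu, `*`)
      ddxm <- sweep(ch, 2, pm * mu^2, `*`) + sweep(sh, 2, qm * mu^2, `*`)
      d3xm <- sweep(sh, 2, pm * mu^3, `*`) + sweep(ch, 2, qm * mu^3, `*`)
      list(x = xm %*% t(Q), dx = dxm %*% t(Q), ddx = ddxm %*% t(Q),
           d3x = d3xm %*% t(Q))
    }
    ev <- eval_modes(times)
    x <- ev$x; dx <- ev$dx; ddx <- ev$ddx; d3x <- ev$d3x
    # report coefficients in the exponential form d1 + d2 t + e^{At} d3 + e^{-At} d4
    d3m <- (pm + qm) * exp(-mu * mid) / 2
    d4m <- (pm - qm) * exp(mu * mid) / 2
    coef <- structure(
      list(d1 = drop(Q %*% d1m), d2 = drop(Q %*% d2m),
           d3 = drop(Q %*% d3m), d4 = drop(Q %*% d4m),
           A = Q %*% (mu * t(Q)), branch = "exponential", T_in = T_in),
      class = "closed_form_coefficients")
    interp <- function(t) eval_modes(t)
  }
  traj <- new_trajectory(times, x, dx, ddx, phase = "inspiration",
                         d3x = d3x, interpolant = interp)
  attr(traj, "coefficients") <- coef
  traj
}

#' @export
print.closed_form_coefficients <- function(x, ...) {
  cat(sprintf("<closed_form_coefficients> %s branch on [0, %g] s\n",
              x$branch, x$T_in))
  for (nm in c("d1", "d2", "d3", "d4"))
    cat(sprintf("  %s: %s\n", nm, paste(signif(x[[nm]], 6), collapse = ", ")))
  invisible(x)
}

#' Inspiratory Euler-Lagrange residual
#'
#' Max-norm over interior grid points of `x'''' - alpha1 R_in x''`. For a
#' trajectory carrying closed-form derivatives (from [solve_inspiration()])
#' all derivatives are analytic; otherwise the third/fourth derivatives are
#' obtained by high-order finite differences of the stored derivatives.
#'
#' @param traj a `lung_trajectory` (at least 5 grid points).
#' @param model a [lung_model()].
#' @param alpha1 inspiratory weight.
#' @return the residual max-norm (l/s^4).
#' @export
inspiration_el_residual <- function(traj, model, alpha1) {
  n <- length(traj$time)
  if (n < 5L) stop("inspiration_el_residual: need at least 5 grid points")
  interior <- 3:(n - 2)
  ti <- traj$time[interior]
  itp <- traj$interpolant
  if (!is.null(itp) && !is.null(itp(traj$time[1])$d3x)) {
    # analytic third derivative available: tight 4th-order stencil for x''''
    dlt <- max(diff(range(traj$time)) * 5e-4, 1e-6)
    d3 <- function(t) itp(t)$d3x
    d4x <- (d3(ti - 2 * dlt) - 8 * d3(ti - dlt) +
              8 * d3(ti + dlt) - d3(ti + 2 * dlt)) / (12 * dlt)
    ddx <- itp(ti)$ddx
  } else {
    h <- traj$time[2] - traj$time[1]
    d3x <- traj$d3x %||% fd_derivative(traj$ddx, h)
    d4x <- fd_derivative(d3x, h)[interior, , drop = FALSE]
    ddx <- traj$ddx[interior, , drop = FALSE]
  }
  res <- d4x - alpha1 * t(model$R_in %*% t(ddx))
  max(abs(res))
}
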