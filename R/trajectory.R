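#' Volume trajectory container
#'
#' All solvers and the forward simulator return a `lung_trajectory`: a time
#' grid with per-compartment volumes, flows and accelerations (third
#' derivatives too when the generator provides them). Use [tidy()] for a long
#' tibble, [glance()] for a one-row summary, and [ggplot2::autoplot()] for a
#' quick plot.
#'
#' @param time strictly increasing time grid (s).
#' @param x,dx,ddx matrices `length(time) x m` of volumes (l), flows (l/s)
#'   and accelerations (l/s^2).
#' @param phase `"inspiration"`, `"expiration"` or `"cycle"`.
#' @param d3x optional third derivatives (l/s^3).
#' @param interpolant optional function `t -> list(x, dx, ddx)` for dense
#'   evaluation.
#' @return an object of class `lung_trajectory`.
#' @keywords internal
#' @export
new_trajectory <- function(time, x, dx, ddx, phase, d3x = NULL,
                           interpolant = NULL) {
  x <- as.matrix(x); dx <- as.matrix(dx); ddx <- as.matrix(ddx)
  stopifnot(length(time) == nrow(x), all(diff(time) > 0))
  if (any(x < -1e-9)) warning("trajectory contains negative volumes")
  structure(list(time = as.numeric(time), x = x, dx = dx, ddx = ddx,
                 d3x = if (!is.null(d3x)) as.matrix(d3x),
                 m = ncol(x), phase = phase, interpolant = interpolant),
            class = "lung_trajectory")
}

#' @export
print.lung_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<lung_trajectory [%s]> %d compartment(s), %d nodes on ",
                     "[%g, %g] s\n  total volume range [%.4g, %.4g] l\n"),
              x$phase, x$m, length(x$time), min(x$time), max(x$time),
              min(rowSums(x$x)), max(rowSums(x$x))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into a long tibble
#'
#' @param x a `lung_trajectory`.
#' @param ... unused.
#' @return a tibble with columns `time_s`, `compartment`, `volume_l`,
#'   `flow_l_per_s`, `accel_l_per_s2`, `phase`.
#' @export
tidy.lung_trajectory <- function(x, ...) {
  m <- x$m; n <- length(x$time)
  phase <- if (length(x$phase) == n) rep(x$phase, m) else x$phase
  tibble::tibble(
    time_s = rep(x$time, m),
    compartment = rep(seq_len(m), each = n),
    volume_l = as.vector(x$x),
    flow_l_per_s = as.vector(x$dx),
    accel_l_per_s2 = as.vector(x$ddx),
    phase = phase)
}

#' @rdname tidy.lung_trajectory
#' @export
glance.lung_trajectory <- function(x, ...) {
  tot <- rowSums(x$x)
  tibble::tibble(
    phase = if (length(x$phase) > 1L) "cycle" else x$phase,
    n_compartments = x$m, n_nodes = length(x$time),
    t_start_s = min(x$time), t_end_s = max(x$time),
    total_volume_min_l = min(tot), total_volume_max_l = max(tot),
    peak_total_flow_l_per_s = max(abs(rowSums(x$dx))))
}

# dense evaluation: closed-form interpolant when available, else C1 cubic
# Hermite from nodal (x, dx)
trajectory_fun <- function(traj) {
  if (!is.null(traj$interpolant)) return(traj$interpolant)
  tg <- traj$time
  function(t) {
    idx <- pmin(pmax(findInterval(t, tg), 1L), length(tg) - 1L)
    h <- tg[idx + 1L] - tg[idx]
    s <- (t - tg[idx]) / h
    h00 <- (1 + 2 * s) * (1 - s)^2; h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s);       h11 <- s^2 * (s - 1)
    x0 <- traj$x[idx, , drop = FALSE]; x1 <- traj$x[idx + 1L, , drop = FALSE]
    d0 <- traj$dx[idx, , drop = FALSE]; d1 <- traj$dx[idx + 1L, , drop = FALSE]
    list(x = h00 * x0 + h01 * x1 + h * (h10 * d0 + h11 * d1))
  }
}

# stack two phase trajectories into one cycle trajectory
bind_trajectories <- function(a, b) {
  keep <- if (isTRUE(all.equal(max(a$time), min(b$time)))) -1L else TRUE
  tb <- if (identical(keep, -1L)) b$time[-1L] else b$time
  sel <- if (identical(keep, -1L)) -1L else seq_len(nrow(b$x))
  new_trajectory(
    time = c(a$time, tb),
    x = rbind(a$x, b$x[sel, , drop = FALSE]),
    dx = rbind(a$dx, b$dx[sel, , drop = FALSE]),
    ddx = rbind(a$ddx, b$ddx[sel, , drop = FALSE]),
    phase = c(rep(a$phase, length(a$time)), rep(b$phase, length(tb))))
}
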