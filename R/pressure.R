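#' Reconstruct the driving pressure from a volume trajectory
#'
#' Inverts the compartmental pressure balance: each compartment's implied
#' airway-opening pressure is `p_i(t) = row_i(R xdot + C(x) x)`. For a
#' trajectory that truly solves the state equation under a single scalar
#' pressure all rows coincide; the `consensus` (mean across compartments)
#' and `spread` (max absolute deviation from the consensus) quantify how
#' realizable the trajectory is by one ventilator pressure.
#'
#' @param traj a `lung_trajectory` with flows.
#' @param model a [lung_model()].
#' @param phase `"inspiration"` or `"expiration"`.
#' @return an object of class `pressure_trace` with fields `time`,
#'   `pressure` (matrix, per compartment, cmH2O), `consensus`, `spread`.
#' @examples
#' fx <- lung_fixture("two_compartment")
#' tr <- solve_inspiration(fx$model, fx$spec)
#' pt <- reconstruct_pressure(tr, fx$model, "inspiration")
#' max(pt$spread)
#' @export
reconstruct_pressure <- function(traj, model,
                                 phase = c("inspiration", "expiration")) {
  phase <- match.arg(phase)
  R <- phase_R(model, phase)
  n <- length(traj$time)
  u <- t(matrix(vapply(seq_len(n), function(k)
    inv_compliance_vec(model, pmax(traj$x[k, ], 0), phase), numeric(model$m)),
    nrow = model$m))
  p <- traj$dx %*% R + u * traj$x
  consensus <- rowMeans(p)
  spread <- apply(abs(p - consensus), 1L, max)
  structure(list(time = traj$time, pressure = p, consensus = consensus,
                 spread = spread, phase = phase),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf(paste0("<pressure_trace [%s]> consensus range [%.4g, %.4g] ",
                     "cmH2O, max spread %.3g cmH2O\n"),
              x$phase, min(x$consensus), max(x$consensus), max(x$spread)))
  invisible(x)
}

#' @rdname reconstruct_pressure
#' @param x a `pressure_trace`.
#' @param ... unused.
#' @export
tidy.pressure_trace <- function(x, ...) {
  m <- ncol(x$pressure); n <- length(x$time)
  tibble::tibble(
    time_s = rep(x$time, m),
    compartment = rep(seq_len(m), each = n),
    pressure_cmH2O = as.vector(x$pressure),
    consensus = rep(x$consensus, m),
    spread = rep(x$spread, m))
}

#' Inspiratory performance functional
#'
#' Composite-Simpson value of the eliminated-pressure inspiratory integrand
#' `xddot' xddot + alpha1 [xdot' R_in xdot + x' C_in(x) xdot]` over the
#' trajectory grid.
#'
#' @param traj an inspiratory `lung_trajectory` on a uniform grid with an
#'   even number of intervals.
#' @param model a [lung_model()].
#' @param alpha1 inspiratory weight.
#' @return scalar `J_in`.
#' @export
performance_inspiration <- function(traj, model, alpha1) {
  if (!identical(traj$phase, "inspiration") && !all(traj$phase == "inspiration"))
    stop("performance_inspiration: trajectory is not an inspiratory phase")
  h <- traj$time[2] - traj$time[1]
  L <- performance_integrand(traj, model, "inspiration", alpha1 = alpha1)
  simpson(L, h)
}

#' Expiratory performance functional
#'
#' Composite-Simpson value of the eliminated-pressure expiratory integrand
#' `xddot' xddot + alpha2 [xdot' R_ex^2 xdot + x' C_ex^2(x) x +
#' 2 xdot' R_ex C_ex(x) x]`.
#'
#' @param traj an expiratory `lung_trajectory` (or `bvp_solution`).
#' @param model a [lung_model()].
#' @param alpha2 expiratory weight.
#' @return scalar `J_ex`.
#' @export
performance_expiration <- function(traj, model, alpha2) {
  if (inherits(traj, "bvp_solution")) traj <- traj$trajectory
  if (!identical(traj$phase, "expiration") && !all(traj$phase == "expiration"))
    stop("performance_expiration: trajectory is not an expiratory phase")
  h <- traj$time[2] - traj$time[1]
  L <- performance_integrand(traj, model, "expiration", alpha2 = alpha2)
  simpson(L, h)
}

# pointwise integrand values along a trajectory
performance_integrand <- function(traj, model, phase, alpha1 = 0, alpha2 = 0) {
  n <- length(traj$time)
  u <- t(matrix(vapply(seq_len(n), function(k)
    inv_compliance_vec(model, pmax(traj$x[k, ], 0), phase), numeric(model$m)),
    nrow = model$m))
  acc <- rowSums(traj$ddx^2)
  if (phase == "inspiration") {
    R <- model$R_in
    acc + alpha1 * (rowSums((traj$dx %*% R) * traj$dx) +
                      rowSums(u * traj$x * traj$dx))
  } else {
    R <- model$R_ex
    Rdx <- traj$dx %*% R
    Cx <- u * traj$x
    acc + alpha2 * (rowSums(Rdx * traj$dx %*% R) + rowSums(Cx^2) +
                      2 * rowSums(Rdx * Cx))
  }
}

#' Solve a full optimal breathing cycle
#'
#' Chains the closed-form inspiratory optimum and the expiratory collocation
#' optimum with shared boundary data: inspiration runs from `V0` to
#' `V0 + VT` on `[0, T_in]`, expiration returns to `V0` on
#' `[T_in, T_in + T_ex]`, so the cycle is periodic by construction.
#'
#' @param model a [lung_model()].
#' @param spec a [breath_spec()].
#' @param n_grid inspiratory output nodes.
#' @param ... passed to [solve_expiration()].
#' @return an object of class `breath_cycle`: list with `inspiration`
#'   (trajectory), `expiration` (`bvp_solution`), `trajectory` (combined),
#'   `pressure` (list of two `pressure_trace`s), `performance` (one-row
#'   tibble with `J_in`, `J_ex`, `J_total`), `model`, `spec`.
#' @examples
#' \donttest{
#' fx <- lung_fixture("two_compartment")
#' cyc <- run_cycle(fx$model, fx$spec)
#' glance(cyc)
#' }
#' @export
run_cycle <- function(model, spec, n_grid = 401L, ...) {
  insp <- solve_inspiration(model, spec, n_grid = n_grid)
  exp_ <- solve_expiration(model, spec, ...)
  J_in <- performance_inspiration(insp, model, spec$alpha1)
  J_ex <- performance_expiration(exp_$trajectory, model, spec$alpha2)
  structure(list(
    inspiration = insp, expiration = exp_,
    trajectory = bind_trajectories(insp, exp_$trajectory),
    pressure = list(
      inspiration = reconstruct_pressure(insp, model, "inspiration"),
      expiration = reconstruct_pressure(exp_$trajectory, model, "expiration")),
    performance = tibble::tibble(J_in = J_in, J_ex = J_ex,
                                 J_total = J_in + J_ex),
    model = model, spec = spec),
    class = "breath_cycle")
}

#' @export
print.breath_cycle <- function(x, ...) {
  cat(sprintf("<breath_cycle> T_in = %g s, T_ex = %g s, %d compartment(s)\n",
              x$spec$T_in, x$spec$T_ex, x$model$m))
  cat(sprintf("  J_in = %.5g, J_ex = %.5g, J_total = %.5g\n",
              x$performance$J_in, x$performance$J_ex, x$performance$J_total))
  invisible(x)
}

#' @rdname run_cycle
#' @param x a `breath_cycle`.
#' @export
glance.breath_cycle <- function(x, ...) {
  tot <- rowSums(x$trajectory$x)
  tibble::tibble(
    x$performance,
    end_expiratory_total_l = min(tot),
    end_inspiratory_total_l = max(tot),
    tidal_excursion_l = sum(x$trajectory$x[which.min(abs(x$trajectory$time - x$spec$T_in)), ]) -
      sum(x$trajectory$x[length(x$trajectory$time), ]),
    max_pressure_spread_cmH2O = max(x$pressure$inspiration$spread,
                                    x$pressure$expiration$spread))
}

#' @rdname run_cycle
#' @export
tidy.breath_cycle <- function(x, ...) tidy(x$trajectory)

#' Limit-cycle analysis of repeated forward-simulated breathing cycles
#'
#' Iterates the cycle map: simulate inspiration under the inspiratory
#' waveform from the current end-expiratory state, then expiration under the
#' expiratory waveform, and feed the end state into the next cycle. Reports
#' the fixed point the iteration converges to and the per-cycle max-norm
#' distances between successive end-expiratory states.
#'
#' @param model a [lung_model()].
#' @param pressures list with `inspiration` and `expiration`
#'   [pressure_waveform()]s (e.g. [reference_pressures()]).
#' @param x0 starting volume vector (l).
#' @param max_cycles iteration cap (default 50).
#' @param tol convergence tolerance on successive end-expiratory states (l).
#' @param n_grid nodes per phase simulation.
#' @return list with `fixed_point` (volume vector), `distances` (per-cycle
#'   max-norm changes), `n_cycles`, `converged`, and `last_cycle` (the final
#'   cycle's combined trajectory).
#' @export
limit_cycle_analysis <- function(model, pressures, x0, max_cycles = 50L,
                                 tol = 1e-6, n_grid = 201L) {
  x <- as.numeric(x0)
  distances <- numeric(0)
  last <- NULL
  for (cyc in seq_len(max_cycles)) {
    insp <- simulate_phase(model, "inspiration", pressures$inspiration, x,
                           n_grid = n_grid)
    ex <- simulate_phase(model, "expiration", pressures$expiration,
                         insp$x[nrow(insp$x), ], n_grid = n_grid)
    xn <- ex$x[nrow(ex$x), ]
    distances <- c(distances, max(abs(xn - x)))
    x <- xn
    last <- bind_trajectories(insp, ex)
    if (distances[cyc] < tol)
      return(list(fixed_point = x, distances = distances, n_cycles = cyc,
                  converged = TRUE, last_cycle = last))
  }
  stop("limit_cycle_analysis: no convergence within ", max_cycles,
       " cycles (distances: ", paste(signif(tail(distances, 6), 3),
                                     collapse = ", "), ")")
}

#' Compare performance of two breathing-cycle bundles
#'
#' Evaluates both phase functionals along each bundle's trajectory and the
#' cumulative criterion `int_0^t L ds` on the common cycle span, the standard
#' optimal-vs-reference diagnostic.
#'
#' @param optimal a `breath_cycle` (from [run_cycle()]) or a list with
#'   `inspiration`/`expiration` trajectories.
#' @param reference same structure (e.g. forward-simulated under
#'   [reference_pressures()]).
#' @param model a [lung_model()].
#' @param spec a [breath_spec()].
#' @return list with `summary` (tibble: label, J_in, J_ex, J_total) and
#'   `cumulative` (tibble: time_s, cumulative_J, label).
#' @export
compare_performance <- function(optimal, reference, model, spec) {
  bundle_traj <- function(b) {
    ins <- if (inherits(b$inspiration, "lung_trajectory")) b$inspiration else b$inspiration$trajectory
    ex <- if (inherits(b$expiration, "bvp_solution")) b$expiration$trajectory else b$expiration
    list(ins = ins, ex = ex)
  }
  one <- function(b, label) {
    tr <- bundle_traj(b)
    Li <- performance_integrand(tr$ins, model, "inspiration", alpha1 = spec$alpha1)
    Le <- performance_integrand(tr$ex, model, "expiration", alpha2 = spec$alpha2)
    hi <- tr$ins$time[2] - tr$ins$time[1]
    he <- tr$ex$time[2] - tr$ex$time[1]
    cum_i <- c(0, cumsum((head(Li, -1) + tail(Li, -1)) / 2 * hi))
    cum_e <- c(0, cumsum((head(Le, -1) + tail(Le, -1)) / 2 * he))
    list(J_in = simpson(Li, hi), J_ex = simpson(Le, he),
         cum = tibble::tibble(
           time_s = c(tr$ins$time, tr$ex$time),
           cumulative_J = c(cum_i, tail(cum_i, 1) + cum_e),
           label = label))
  }
  a <- one(optimal, "optimal"); b <- one(reference, "reference")
  list(summary = tibble::tibble(
    label = c("optimal", "reference"),
    J_in = c(a$J_in, b$J_in), J_ex = c(a$J_ex, b$J_ex),
    J_total = c(a$J_in + a$J_ex, b$J_in + b$J_ex)),
    cumulative = rbind(a$cum, b$cum))
}
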