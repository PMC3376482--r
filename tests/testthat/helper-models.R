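# shared builders for the test suite

# near-constant compliance curve: plateau c0 from ~0 volume up to far beyond
# the volumes any test visits, so 1/c is constant and its derivative ~ 0
const_curve <- function(c0, phase = "expiration") {
  compliance_curve(a1 = c0 - 0.001, b1 = 1, a2 = c0,
                   a3 = c0 + 0.05, b3 = -0.001,
                   x1 = 0.001, x2 = 50, v_cap = 100,
                   beta_smooth = 200, phase = phase)
}

# single-compartment model with constant compliances
single_comp_model <- function(R_in = 1.5, R_ex = 3.0, c_in = 0.05,
                              c_ex = c_in) {
  tr <- airway_tree(0, list(R_in))
  tre <- airway_tree(0, list(R_ex))
  lung_model(tr, tre, const_curve(c_in, "inspiration"),
             const_curve(c_ex, "expiration"))
}

# two-compartment constant-compliance model (mild, no boundary layers)
mild_two_comp <- function(c0 = 0.5) {
  tr <- airway_tree(1, list(1.0, c(1.0, 1.0)))
  lung_model(tr, lungflow:::scale_tree(tr, 2.5),
             const_curve(c0, "inspiration"), const_curve(c0, "expiration"))
}

published_fixture <- function(...) lung_fixture("two_compartment", ...)

# analytic solution of the constant-coefficient linear expiratory BVP
# x'''' - a2 R^2 x'' + a2 C^2 x = 0 with clamped boundary data
linear_expiration_exact <- function(tt, t0, t1, x_start, x_end, R, C, a2) {
  r <- polyroot(c(a2 * C^2, 0, -a2 * R^2, 0, 1))
  M <- sapply(1:4, function(k) exp(r[k] * (tt - t0)))
  Md <- sapply(1:4, function(k) r[k] * exp(r[k] * (tt - t0)))
  n <- length(tt)
  A <- rbind(M[1, ], Md[1, ], M[n, ], Md[n, ])
  Re(M %*% solve(A, c(x_start, 0, x_end, 0)))
}

# cached expensive solves shared across test files
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fixture_cycle <- function() cached("cycle", {
  fx <- published_fixture()
  suppressWarnings(run_cycle(fx$model, fx$spec))
})

fixture_expiration <- function() fixture_cycle()$expiration

# smooth admissible perturbation vanishing with its first derivative at both
# endpoints: s^2 (1-s)^2 times a low-order random trigonometric polynomial
random_perturbation <- function(times, m, amplitude = 0.02) {
  t0 <- times[1]; t1 <- times[length(times)]
  s <- (times - t0) / (t1 - t0)
  env2 <- (s * (1 - s))^2
  denv2 <- 2 * s * (1 - s) * (1 - 2 * s) / (t1 - t0)
  d2env2 <- (2 - 12 * s + 12 * s^2) / (t1 - t0)^2
  sapply(seq_len(m), function(i) {
    a <- stats::rnorm(3, sd = amplitude)
    om <- (1:3) * pi / (t1 - t0)
    f <- drop(cos(outer(times - t0, om)) %*% a)
    df <- drop(-sin(outer(times - t0, om)) %*% (a * om))
    d2f <- drop(-cos(outer(times - t0, om)) %*% (a * om^2))
    cbind(env2 * f, denv2 * f + env2 * df,
          d2env2 * f + 2 * denv2 * df + env2 * d2f)
  }, simplify = "array")
}

# add a perturbation array (from random_perturbation) to a trajectory
perturb_trajectory <- function(traj, pert) {
  suppressWarnings(lungflow:::new_trajectory(
    traj$time,
    traj$x + pert[, 1, ], traj$dx + pert[, 2, ], traj$ddx + pert[, 3, ],
    phase = traj$phase))
}
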