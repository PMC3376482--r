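test_that("inspiratory functional of the zero-weight cubic matches the closed form", {
  fx <- published_fixture()
  sp <- fx$spec; sp$alpha1 <- 0
  traj <- solve_inspiration(fx$model, sp)
  # per compartment int (6 VT/T^2 - 12 VT t/T^3)^2 dt = 12 VT^2 / T^3
  expect_equal(performance_inspiration(traj, fx$model, 0),
               2 * 12 * 0.6^2 / 2^3, tolerance = 1e-10)
  # quadrature refinement changes nothing appreciable
  fine <- solve_inspiration(fx$model, fx$spec, n_grid = 801)
  coarse <- solve_inspiration(fx$model, fx$spec, n_grid = 401)
  J1 <- performance_inspiration(coarse, fx$model, 2)
  J2 <- performance_inspiration(fine, fx$model, 2)
  expect_lt(abs(J1 - J2) / J1, 1e-8)
})

test_that("expiratory functional of the Hermite cubic matches the closed form", {
  fx <- published_fixture()
  sp <- fx$spec; sp$alpha2 <- 0
  sol <- suppressWarnings(solve_expiration(fx$model, sp))
  expect_equal(performance_expiration(sol, fx$model, 0),
               2 * 12 * 0.6^2 / 3^3, tolerance = 1e-10)
})

test_that("a static equilibrium trajectory costs only its potential term", {
  c0 <- 0.05; x0 <- 0.3; a2 <- 0.1
  mdl <- single_comp_model(c_ex = c0)
  times <- seq(2, 5, length.out = 101)
  traj <- lungflow:::new_trajectory(times, matrix(x0, 101, 1),
                                    matrix(0, 101, 1), matrix(0, 101, 1),
                                    phase = "expiration")
  p <- x0 / c0
  expect_equal(performance_expiration(traj, mdl, a2), a2 * p^2 * 1 * 3,
               tolerance = 1e-6)
})

test_that("phase mismatch is rejected", {
  fx <- published_fixture()
  traj <- solve_inspiration(fx$model, fx$spec)
  expect_error(performance_expiration(traj, fx$model, 0.1), "not an expiratory")
  expect_error(performance_inspiration(fixture_expiration()$trajectory,
                                       fx$model, 2), "not an inspiratory")
})

test_that("identical compartments yield coincident reconstructed pressures", {
  fx <- published_fixture()
  cyc <- fixture_cycle()
  expect_lt(max(cyc$pressure$inspiration$spread), 1e-8)
  expect_lt(max(cyc$pressure$expiration$spread), 1e-8)
})

test_that("a full cycle is continuous at the phase switch and periodic", {
  fx <- published_fixture()
  cyc <- fixture_cycle()
  ins <- cyc$inspiration; ex <- cyc$expiration$trajectory
  expect_equal(ins$x[nrow(ins$x), ], ex$x[1, ], tolerance = 1e-12)
  expect_equal(cyc$trajectory$x[1, ], fx$spec$V0, tolerance = 1e-9)
  n <- length(cyc$trajectory$time)
  expect_equal(cyc$trajectory$x[n, ], fx$spec$V0, tolerance = 1e-7)
  # total volume spans the full tidal range
  tot <- rowSums(cyc$trajectory$x)
  expect_equal(max(tot), sum(fx$spec$V0 + fx$spec$VT), tolerance = 1e-6)
  g <- glance(cyc)
  expect_equal(g$tidal_excursion_l, 1.2, tolerance = 1e-6)
})

test_that("repeated reference cycles contract to a limit cycle", {
  fx <- published_fixture()
  pr <- reference_pressures(2, 3)
  lc <- limit_cycle_analysis(fx$model, pr, x0 = c(0.1, 0.1), tol = 1e-6)
  expect_true(lc$converged)
  expect_lte(lc$n_cycles, 20)
  expect_true(all(diff(lc$distances) < 0))
  # restarting on the fixed point converges in a single cycle
  lc2 <- limit_cycle_analysis(fx$model, pr, x0 = lc$fixed_point, tol = 1e-6)
  expect_equal(lc2$n_cycles, 1L)
})

test_that("the single-compartment cycle map fixed point matches the affine closed form", {
  R_in <- 1.5; R_ex <- 3.0; c0 <- 0.2
  mdl <- single_comp_model(R_in = R_in, R_ex = R_ex, c_in = c0, c_ex = c0)
  pr <- reference_pressures(2, 3)
  lc <- limit_cycle_analysis(mdl, pr, x0 = 0.05, tol = 1e-9, n_grid = 301)
  # inspiration under p = 20 t + 5: steady ramp solution plus decaying mode,
  # then passive decay; fixed point of the composite affine map
  tau_i <- R_in * c0; tau_e <- R_ex * c0
  ramp <- function(t) c0 * (20 * t + 5) - R_in * c0^2 * 20
  xTin <- function(x0) ramp(2) + (x0 - ramp(0)) * exp(-2 / tau_i)
  a <- exp(-2 / tau_i) * exp(-3 / tau_e)
  b <- (ramp(2) - ramp(0) * exp(-2 / tau_i)) * exp(-3 / tau_e)
  expect_equal(lc$fixed_point, b / (1 - a), tolerance = 1e-6)
})

test_that("performance comparison favours the optimal cycle and accumulates monotonically", {
  fx <- published_fixture()
  cyc <- fixture_cycle()
  pr <- reference_pressures(2, 3)
  ins <- simulate_phase(fx$model, "inspiration", pr$inspiration, x0 = fx$spec$V0)
  ex <- simulate_phase(fx$model, "expiration", pr$expiration,
                       x0 = ins$x[nrow(ins$x), ])
  cmp <- compare_performance(cyc, list(inspiration = ins, expiration = ex),
                             fx$model, fx$spec)
  s <- cmp$summary
  expect_lt(s$J_total[s$label == "optimal"], s$J_total[s$label == "reference"])
  # optimal against itself: identical summaries and curves
  self <- compare_performance(cyc, cyc, fx$model, fx$spec)
  expect_equal(self$summary$J_total[1], self$summary$J_total[2])
  # cumulative criterion is nondecreasing (nonnegative integrands here)
  opt_curve <- cmp$cumulative[cmp$cumulative$label == "optimal", ]
  expect_true(all(diff(opt_curve$cumulative_J) > -1e-9))
})
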