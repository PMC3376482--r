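test_that("forward simulation matches the single-compartment closed form", {
  R <- 1.5; c0 <- 0.05; p0 <- 10; x0 <- 0.15
  mdl <- single_comp_model(R_in = R, c_in = c0)
  wf <- pressure_waveform(function(t) rep(p0, length(t)), 0, 2, "step")
  traj <- simulate_phase(mdl, "inspiration", wf, x0 = x0, n_grid = 201)
  exact <- c0 * p0 + (x0 - c0 * p0) * exp(-traj$time / (R * c0))
  expect_lt(max(abs(traj$x[, 1] - exact)) / max(exact), 1e-6)
})

test_that("an equilibrium initial state stays put under matching pressure", {
  c0 <- 0.05; p0 <- 8
  mdl <- single_comp_model(c_in = c0)
  wf <- pressure_waveform(function(t) rep(p0, length(t)), 0, 3, "hold")
  traj <- simulate_phase(mdl, "inspiration", wf, x0 = c0 * p0, n_grid = 101)
  expect_lt(max(abs(traj$x - c0 * p0)), 1e-7)
  expect_lt(max(abs(traj$dx)), 1e-6)
})

test_that("the reference linear ramp inflates the published fixture monotonically", {
  fx <- published_fixture()
  pr <- reference_pressures(fx$spec$T_in, fx$spec$T_ex)
  traj <- simulate_phase(fx$model, "inspiration", pr$inspiration,
                         x0 = fx$spec$V0)
  expect_equal(pr$inspiration(0), 5)
  expect_equal(pr$inspiration(2), 45)
  expect_equal(pr$expiration(c(2.5, 4)), c(0, 0))
  expect_true(all(diff(rowSums(traj$x)) > 0))
})

test_that("waveforms refuse evaluation outside their phase domain", {
  pr <- reference_pressures(2, 3)
  expect_error(pr$inspiration(2.5), "domain")
  expect_error(pr$expiration(1.0), "domain")
})

test_that("tightening integrator tolerances barely moves the endpoint", {
  fx <- published_fixture()
  pr <- reference_pressures(2, 3)
  a <- simulate_phase(fx$model, "inspiration", pr$inspiration,
                      x0 = fx$spec$V0, rtol = 1e-8, atol = 1e-10)
  b <- simulate_phase(fx$model, "inspiration", pr$inspiration,
                      x0 = fx$spec$V0, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(a$x[nrow(a$x), ] - b$x[nrow(b$x), ])), 1e-7)
})

test_that("permuting identical sibling compartments permutes the solution", {
  fx <- published_fixture()
  pr <- reference_pressures(2, 3)
  a <- simulate_phase(fx$model, "inspiration", pr$inspiration,
                      x0 = c(0.05, 0.15), n_grid = 101)
  b <- simulate_phase(fx$model, "inspiration", pr$inspiration,
                      x0 = c(0.15, 0.05), n_grid = 101)
  expect_equal(a$x[, 1], b$x[, 2], tolerance = 1e-9)
  expect_equal(a$x[, 2], b$x[, 1], tolerance = 1e-9)
})

test_that("pressure reconstruction inverts forward simulation", {
  fx <- published_fixture()
  pr <- reference_pressures(2, 3)
  traj <- simulate_phase(fx$model, "inspiration", pr$inspiration,
                         x0 = fx$spec$V0)
  pt <- reconstruct_pressure(traj, fx$model, "inspiration")
  expect_lt(max(abs(pt$consensus - (20 * traj$time + 5))), 1e-6)
  expect_lt(max(pt$spread), 1e-6)
  # single compartment: consensus is exactly R xdot + x / c(x)
  mdl <- single_comp_model(c_in = 0.05)
  wf <- pressure_waveform(function(t) 4 + 2 * t, 0, 2, "ramp")
  tr1 <- simulate_phase(mdl, "inspiration", wf, x0 = 0.1, n_grid = 101)
  p1 <- reconstruct_pressure(tr1, mdl, "inspiration")
  expect_equal(p1$consensus,
               1.5 * tr1$dx[, 1] + tr1$x[, 1] / 0.05, tolerance = 1e-5)
  expect_equal(max(p1$spread), 0)
})

test_that("trajectories tidy into the documented long format", {
  fx <- published_fixture()
  pr <- reference_pressures(2, 3)
  traj <- simulate_phase(fx$model, "inspiration", pr$inspiration,
                         x0 = fx$spec$V0, n_grid = 51)
  td <- tidy(traj)
  expect_named(td, c("time_s", "compartment", "volume_l", "flow_l_per_s",
                     "accel_l_per_s2", "phase"))
  expect_equal(nrow(td), 51 * 2)
  g <- glance(traj)
  expect_equal(g$n_compartments, 2L)
  expect_equal(g$t_end_s, 2)
})
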