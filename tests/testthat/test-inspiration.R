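test_that("zero-weight inspiration returns the minimum-acceleration cubic exactly", {
  fx <- published_fixture()
  sp <- fx$spec; sp$alpha1 <- 0
  traj <- solve_inspiration(fx$model, sp)
  cf <- attr(traj, "coefficients")
  expect_equal(cf$branch, "cubic")
  expect_equal(cf$d1, sp$V0, tolerance = 1e-10)
  expect_equal(cf$d2, rep(0, 2), tolerance = 1e-10)
  expect_equal(cf$d3, 3 * sp$VT / sp$T_in^2, tolerance = 1e-10)
  expect_equal(cf$d4, -2 * sp$VT / sp$T_in^3, tolerance = 1e-10)
  # midpoint flow of the cubic: 1.5 VT / T_in per compartment
  mid <- which.min(abs(traj$time - 1))
  expect_equal(traj$dx[mid, ], rep(0.45, 2), tolerance = 1e-9)
})

test_that("boundary conditions hold for all weights", {
  fx <- published_fixture()
  n <- 401
  for (a1 in c(0, 0.5, 2, 10)) {
    sp <- fx$spec; sp$alpha1 <- a1
    traj <- solve_inspiration(fx$model, sp)
    expect_equal(traj$x[1, ], sp$V0, tolerance = 1e-9)
    expect_equal(traj$x[n, ], sp$V0 + sp$VT, tolerance = 1e-9)
    expect_lt(max(abs(traj$dx[1, ])), 1e-9)
    expect_lt(max(abs(traj$dx[n, ])), 1e-9)
    # volumes nondecreasing throughout inspiration
    expect_true(all(diff(traj$x[, 1]) > -1e-10))
  }
})

test_that("the exponential branch degenerates to the cubic as alpha1 -> 0", {
  fx <- published_fixture()
  sp0 <- fx$spec; sp0$alpha1 <- 0
  spE <- fx$spec; spE$alpha1 <- 1e-8
  a <- solve_inspiration(fx$model, sp0)
  b <- solve_inspiration(fx$model, spE)
  expect_equal(attr(b, "coefficients")$branch, "exponential")
  expect_lt(max(abs(a$x - b$x)), 1e-5)
})

test_that("the closed form satisfies its Euler-Lagrange equation", {
  fx <- published_fixture()
  traj <- solve_inspiration(fx$model, fx$spec)
  expect_lt(inspiration_el_residual(traj, fx$model, fx$spec$alpha1), 1e-8)
  sp0 <- fx$spec; sp0$alpha1 <- 0
  cub <- solve_inspiration(fx$model, sp0)
  expect_lt(inspiration_el_residual(cub, fx$model, 0), 1e-10)
  # negative control: the cubic does not satisfy the alpha1 > 0 equation
  expect_gt(inspiration_el_residual(cub, fx$model, 2.0), 1e-3)
})

test_that("total inspiratory flow is symmetric about mid-inspiration", {
  fx <- published_fixture()
  traj <- solve_inspiration(fx$model, fx$spec)
  tot <- rowSums(traj$dx)
  expect_lt(max(abs(tot - rev(tot))), 1e-6)
})

test_that("peak inspiratory flow decreases as the work weight grows", {
  fx <- published_fixture()
  peaks <- sapply(c(0.5, 2.0, 8.0), function(a1) {
    sp <- fx$spec; sp$alpha1 <- a1
    max(rowSums(solve_inspiration(fx$model, sp)$dx))
  })
  expect_true(all(diff(peaks) < 0))
})

test_that("the optimal inspiration is independent of compliance", {
  fx <- published_fixture()
  a <- solve_inspiration(fx$model, fx$spec)
  other <- lung_model(fx$model$tree_in, fx$model$tree_ex,
                      const_curve(0.01, "inspiration"),
                      fx$model$compliance_ex)
  b <- solve_inspiration(other, fx$spec)
  expect_equal(a$x, b$x, tolerance = 1e-12)
})

test_that("grids too coarse for the residual check are rejected", {
  fx <- published_fixture()
  traj <- solve_inspiration(fx$model, fx$spec, n_grid = 4)
  expect_error(inspiration_el_residual(traj, fx$model, 2), "5 grid points")
})
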