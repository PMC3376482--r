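test_that("zero-weight expiration is the Hermite cubic with vanishing fourth derivative", {
  fx <- published_fixture()
  sp <- fx$spec; sp$alpha2 <- 0
  sol <- suppressWarnings(solve_expiration(fx$model, sp))
  tr <- sol$trajectory
  n <- length(tr$time)
  expect_true(sol$converged)
  expect_equal(tr$x[1, ], sp$V0 + sp$VT, tolerance = 1e-12)
  expect_equal(tr$x[n, ], sp$V0, tolerance = 1e-12)
  expect_lt(max(abs(tr$dx[1, ])), 1e-12)
  expect_lt(max(abs(tr$dx[n, ])), 1e-12)
  # third derivative constant => fourth derivative identically zero
  expect_lt(max(abs(diff(tr$d3x[, 1]))), 1e-10)
  expect_lt(suppressWarnings(expiration_el_residual(tr, fx$model, 0)), 1e-9)
  # volumes nonincreasing (the zero-weight optimum is monotone)
  expect_true(all(diff(tr$x[, 1]) < 1e-12))
})

test_that("collocation matches the analytic linear single-compartment solution", {
  mdl <- single_comp_model(R_in = 1.5, R_ex = 3.0, c_in = 0.5, c_ex = 0.5)
  sp <- breath_spec(2, 3, V0 = 0.4, VT = 0.5, alpha1 = 1, alpha2 = 0.1)
  sol <- solve_expiration(mdl, sp, n_mesh = 401, adapt = 0)
  exact <- linear_expiration_exact(sol$mesh, 2, 5, 0.9, 0.4,
                                   R = 3.0, C = 2, a2 = 0.1)
  expect_lt(max(abs(exact - sol$solver_trajectory$x)), 1e-6)
  expect_lt(sol$el_residual, 1e-5)
})

test_that("mesh refinement leaves the solution unchanged at tolerance level", {
  mdl <- mild_two_comp()
  sp <- breath_spec(2, 3, V0 = c(0.3, 0.3), VT = c(0.3, 0.3),
                    alpha1 = 1, alpha2 = 0.1)
  a <- solve_expiration(mdl, sp, n_mesh = 301, adapt = 0, n_out = 201)
  b <- solve_expiration(mdl, sp, n_mesh = 601, adapt = 0, n_out = 201)
  expect_lt(max(abs(a$trajectory$x - b$trajectory$x)), 1e-6)
})

test_that("converged fixture collocation satisfies the Euler-Lagrange equation", {
  sol <- fixture_expiration()
  expect_true(sol$converged)
  expect_lt(sol$el_residual, 1e-5)
  expect_equal(expiration_el_residual(sol, NULL, NULL), sol$el_residual)
  tr <- sol$trajectory
  n <- length(tr$time)
  fx <- published_fixture()
  expect_equal(tr$x[1, ], fx$spec$V0 + fx$spec$VT, tolerance = 1e-7)
  expect_equal(tr$x[n, ], fx$spec$V0, tolerance = 1e-7)
  expect_lt(max(abs(tr$dx[1, ]), abs(tr$dx[n, ])), 1e-7)
})

test_that("expiratory flow has an early trough that steepens with alpha2", {
  fx <- published_fixture()
  sol <- fixture_expiration()
  tot <- rowSums(sol$trajectory$dx)
  t_tr <- sol$trajectory$time[which.min(tot)]
  expect_lt(t_tr, fx$spec$T_in + fx$spec$T_ex / 2)  # first half of expiration
  troughs <- sapply(c(0.05, 0.2), function(a2) {
    sp <- fx$spec; sp$alpha2 <- a2
    s <- suppressWarnings(solve_expiration(fx$model, sp, n_mesh = 1001,
                                           adapt = 1))
    min(rowSums(s$trajectory$dx))
  })
  expect_lt(troughs[2], troughs[1])
})

test_that("linear regime classification matches the critical weight", {
  expect_equal(classify_linear_regime(0, 2, 5)$regime, 1L)
  crit <- 4 * 5^2 / 2^4
  expect_equal(classify_linear_regime(crit, 2, 5)$regime, 3L)
  expect_equal(classify_linear_regime(crit * 0.5, 2, 5)$regime, 2L)
  expect_equal(classify_linear_regime(5, 1, 1)$regime, 4L)
  expect_equal(classify_linear_regime(0.1, 2, 5)$label, "oscillatory")
  expect_error(classify_linear_regime(0.1, -1, 5), "positive")
})

test_that("the published expiratory cubic coefficients are reproduced verbatim", {
  sp <- breath_spec(2, 3, V0 = c(0.1, 0.1), VT = c(0.6, 0.6))
  cf <- expiration_reference_cubic(sp)
  expect_equal(cf$beta_cubic, 1 / 473)
  expect_equal(cf$d4, -2 * sp$VT / 473)
  expect_equal(cf$d2, -(6 * 4 * sp$VT + 6 * 3 * 2 * sp$VT) / 473)
  # the published form meets the start volume and both zero-flow conditions
  # exactly, but misses the end volume by a wide margin
  rep_ <- cf$boundary_report
  get <- function(cond) rep_$achieved[rep_$condition == cond]
  expect_lt(get("x(T_in) = V0 + VT"), 1e-12)
  expect_lt(get("xdot(T_in) = 0"), 1e-12)
  expect_lt(get("xdot(T_in + T_ex) = 0"), 1e-12)
  expect_gt(get("x(T_in + T_ex) = V0"), 0.5)
  # while the solver's Hermite cubic satisfies all four conditions
  fx <- published_fixture()
  sp0 <- fx$spec; sp0$alpha2 <- 0
  tr <- suppressWarnings(solve_expiration(fx$model, sp0))$trajectory
  expect_lt(max(abs(tr$dx[1, ])), 1e-12)
  expect_equal(tr$x[length(tr$time), ], sp0$V0, tolerance = 1e-12)
})

test_that("manufactured forcing validates the Euler-Lagrange operator", {
  fx <- published_fixture()
  chk <- manufactured_residual_check(fx$model, fx$spec)
  expect_lt(chk$max_discrepancy, 1e-6)
  # alpha2 = 0 reduces the operator to the bare fourth derivative of the
  # manufactured trajectory, amp * om^4 * cos(om (t - T_in))
  sp0 <- fx$spec; sp0$alpha2 <- 0
  n <- 801
  chk0 <- manufactured_residual_check(fx$model, sp0, n_grid = n)
  tt <- seq(0, sp0$T_ex, length.out = n)[3:(n - 2)]
  d4_exact <- sapply(c(1.3, 2.1), function(om) 0.15 * om^4 * cos(om * tt))
  expect_equal(chk0$analytic, d4_exact, tolerance = 1e-10)
})

test_that("a constant state reduces the operator to its potential terms", {
  mdl <- single_comp_model(R_ex = 3, c_ex = 0.05)
  x0 <- 0.3; a2 <- 0.1
  Y <- matrix(c(x0, 0, 0, 0), 1, 4)
  F <- lungflow:::expiration_rhs(Y, mdl, a2)
  u <- 1 / compliance_value(mdl$compliance_ex[[1]], x0)
  du <- inv_compliance_derivative(mdl$compliance_ex[[1]], x0)
  expect_equal(F[1, 4], -a2 * (u^2 * x0 + du * u * x0^2), tolerance = 1e-10)
})
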