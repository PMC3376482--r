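# the published inspiratory curve is discontinuous at its upper breakpoint,
# so building it warns; tests that only need a valid curve suppress that
insp_curve <- function() suppressWarnings(
  compliance_curve(a1 = 0.018, b1 = 0.0233, a2 = 0.025, a3 = 0.2532,
                   b3 = -0.01, x1 = 0.3, x2 = 0.48, v_cap = 0.6,
                   phase = "inspiration"))
ex_curve <- function(beta = 30)
  compliance_curve(a1 = 0.02, b1 = 0.078, a2 = 0.038, a3 = 0.1025,
                   b3 = -0.15, x1 = 0.23, x2 = 0.43, v_cap = 0.6,
                   beta_smooth = beta, phase = "expiration")

test_that("piecewise compliance reproduces the published plateau and segment values", {
  cc <- insp_curve()
  expect_equal(compliance_value(cc, 0.4, "piecewise"), 0.025)
  # left-closed tie-break: value at x1 comes from segment 1
  expect_equal(compliance_value(cc, 0.3, "piecewise"), 0.018 + 0.0233 * 0.3)
  # rising segment and affine extension of segment 3 beyond v_cap
  expect_equal(compliance_value(cc, 0.1, "piecewise"), 0.018 + 0.0233 * 0.1)
  expect_equal(compliance_value(cc, 0.65, "piecewise"), 0.2532 - 0.01 * 0.65)
  ce <- ex_curve()
  expect_equal(compliance_value(ce, 0.3, "piecewise"), 0.038)
  # the published expiratory curve is continuous at its upper breakpoint and
  # nearly so (0.16 percent) at the lower one
  expect_equal(0.1025 - 0.15 * 0.43, 0.038, tolerance = 1e-10)
  expect_equal(0.02 + 0.078 * 0.23, 0.038, tolerance = 2e-3)
})

test_that("smoothed compliance tracks the piecewise curve away from breakpoints", {
  ce <- ex_curve(30)
  xs <- seq(0.02, 0.6, by = 0.01)
  away <- abs(xs - 0.23) >= 0.05 & abs(xs - 0.43) >= 0.05
  pw <- compliance_value(ce, xs, "piecewise")
  sm <- compliance_value(ce, xs, "smoothed")
  expect_lt(max(abs(sm[away] - pw[away]) / pw[away]), 0.05)
})

test_that("smoothed compliance converges pointwise to piecewise as beta grows", {
  xs <- c(0.1, 0.3, 0.35, 0.5, 0.55)
  errs <- sapply(c(30, 100, 300), function(b) {
    ce <- ex_curve(b)
    max(abs(compliance_value(ce, xs, "smoothed") -
              compliance_value(ce, xs, "piecewise")))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("reciprocal-compliance derivative matches central differences", {
  ce <- ex_curve()
  xs <- seq(0.05, 0.6, by = 0.05)
  h <- 1e-5
  num <- (1 / compliance_value(ce, xs + h) - 1 / compliance_value(ce, xs - h)) / (2 * h)
  ana <- inv_compliance_derivative(ce, xs)
  expect_lt(max(abs(ana - num) / pmax(abs(num), 1e-8)), 1e-4)
})

test_that("reciprocal-compliance derivative vanishes on plateaus and for constant curves", {
  hard <- compliance_curve(a1 = 0.01, b1 = 0.1, a2 = 0.04, a3 = 0.28,
                           b3 = -0.4, x1 = 0.3, x2 = 0.6, v_cap = 1,
                           beta_smooth = 500)
  expect_lt(abs(inv_compliance_derivative(hard, 0.45)), 1e-6)
  cc <- const_curve(0.05)
  expect_lt(max(abs(inv_compliance_derivative(cc, c(0.1, 0.3, 0.6)))), 1e-5)
})

test_that("curve validation rejects bad parameters and flags discontinuity", {
  expect_error(compliance_curve(0.02, -0.1, 0.04, 0.1, -0.1, 0.2, 0.4, 1), "b1")
  expect_error(compliance_curve(0.02, 0.1, 0.04, 0.1, 0.1, 0.2, 0.4, 1), "b3")
  expect_error(compliance_curve(0.02, 0.1, 0.04, 0.1, -0.1, 0.4, 0.2, 1), "x1")
  expect_warning(
    compliance_curve(a1 = 0.018, b1 = 0.0233, a2 = 0.025, a3 = 0.2532,
                     b3 = -0.01, x1 = 0.3, x2 = 0.48, v_cap = 0.6),
    "discontinuous")
  expect_error(compliance_value(ex_curve(), -0.1), "nonnegative")
})
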