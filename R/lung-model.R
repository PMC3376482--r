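#' Multicompartment lung mechanics model
#'
#' Bundles the phase-specific airway trees and per-compartment compliance
#' curves of a `2^n`-compartment lung. The pressure balance during
#' inspiration is `R_in xdot + C_in(x) x = p_in(t) e` and during (passive)
#' expiration `R_ex xdot + C_ex(x) x = p_ex(t) e`, where `C(x)` is the
#' diagonal matrix of reciprocal compliances and `R` the tree resistance
#' matrix.
#'
#' @param tree_in,tree_ex [airway_tree()] objects for inspiration and
#'   expiration (same depth `n`).
#' @param compliance_in,compliance_ex lists of `2^n` [compliance_curve()]s,
#'   one per compartment (a single curve is recycled).
#' @return an object of class `lung_model` with precomputed resistance
#'   matrices `R_in`, `R_ex` and compartment count `m`.
#' @export
lung_model <- function(tree_in, tree_ex, compliance_in, compliance_ex) {
  stopifnot(inherits(tree_in, "airway_tree"), inherits(tree_ex, "airway_tree"))
  if (tree_in$n != tree_ex$n)
    stop("lung_model: inspiratory and expiratory trees must share n")
  m <- 2^tree_in$n
  recycle <- function(cc, phase) {
    if (inherits(cc, "compliance_curve")) cc <- list(cc)
    if (length(cc) == 1L) cc <- rep(cc, m)
    if (length(cc) != m)
      stop("lung_model: need 1 or ", m, " ", phase, " compliance curves")
    stopifnot(all(vapply(cc, inherits, logical(1), "compliance_curve")))
    cc
  }
  compliance_in <- recycle(compliance_in, "inspiratory")
  compliance_ex <- recycle(compliance_ex, "expiratory")
  R_in <- resistance_matrix(tree_in)
  R_ex <- resistance_matrix(tree_ex)
  for (R in list(R_in, R_ex)) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("lung_model: resistance matrix not positive definite")
  }
  structure(list(n = tree_in$n, m = m,
                 tree_in = tree_in, tree_ex = tree_ex,
                 compliance_in = compliance_in, compliance_ex = compliance_ex,
                 R_in = R_in, R_ex = R_ex),
            class = "lung_model")
}

#' @export
print.lung_model <- function(x, ...) {
  cat(sprintf("<lung_model> %d compartment(s), %d generation(s)\n", x$m, x$n))
  cat(sprintf("  R_in eigenvalues: %s cmH2O s/l\n",
              paste(signif(eigen(x$R_in, symmetric = TRUE,
                                 only.values = TRUE)$values, 4),
                    collapse = ", ")))
  invisible(x)
}

phase_R <- function(model, phase) {
  switch(phase, inspiration = model$R_in, expiration = model$R_ex,
         stop("phase must be 'inspiration' or 'expiration'"))
}

phase_curves <- function(model, phase) {
  switch(phase, inspiration = model$compliance_in,
         expiration = model$compliance_ex,
         stop("phase must be 'inspiration' or 'expiration'"))
}

# reciprocal compliances 1/c_i(x_i) as a vector (the diagonal of C(x))
inv_compliance_vec <- function(model, x, phase) {
  curves <- phase_curves(model, phase)
  vapply(seq_len(model$m), function(i) {
    ci <- compliance_value(curves[[i]], x[i])
    if (ci <= 0) stop("compliance is zero in compartment ", i)
    1 / ci
  }, numeric(1))
}

# d/dx_i (1/c_i(x_i)) as a vector (the diagonal of C'(x))
inv_compliance_deriv_vec <- function(model, x, phase) {
  curves <- phase_curves(model, phase)
  vapply(seq_len(model$m), function(i)
    inv_compliance_derivative(curves[[i]], x[i]), numeric(1))
}

#' Diagonal reciprocal-compliance matrix C(x)
#'
#' @param model a [lung_model()].
#' @param x volume vector (l), length `m`, nonnegative.
#' @param phase `"inspiration"` or `"expiration"`.
#' @return diagonal `m x m` matrix with entries `1/c_i(x_i)` (cmH2O/l),
#'   smoothed compliance.
#' @export
compliance_matrix <- function(model, x,
                              phase = c("inspiration", "expiration")) {
  phase <- match.arg(phase)
  if (length(x) != model$m)
    stop("compliance_matrix: x must have length ", model$m)
  if (any(x < 0)) stop("compliance_matrix: volumes must be nonnegative")
  diag(inv_compliance_vec(model, x, phase), nrow = model$m)
}

#' Breath timing, boundary volumes and optimization weights
#'
#' @param T_in,T_ex inspiratory and expiratory durations (s), positive.
#' @param V0 end-expiratory volume vector (l), nonnegative; recycled to the
#'   compartment count when a model is attached downstream.
#' @param VT tidal volume vector (l), strictly positive.
#' @param alpha1 inspiratory work-of-breathing weight (l/(s^3 cmH2O)), >= 0.
#' @param alpha2 expiratory squared-pressure weight (l^2/(s^4 cmH2O)), >= 0.
#' @return an object of class `breath_spec`.
#' @export
breath_spec <- function(T_in, T_ex, V0, VT, alpha1 = 2.0, alpha2 = 0.1) {
  if (!(T_in > 0) || !(T_ex > 0)) stop("breath_spec: durations must be positive")
  if (alpha1 < 0 || alpha2 < 0) stop("breath_spec: weights must be nonnegative")
  if (any(V0 < 0)) stop("breath_spec: V0 must be nonnegative")
  if (any(VT <= 0)) stop("breath_spec: VT must be strictly positive")
  if (length(V0) != length(VT)) stop("breath_spec: V0 and VT lengths differ")
  structure(list(T_in = T_in, T_ex = T_ex, V0 = as.numeric(V0),
                 VT = as.numeric(VT), alpha1 = alpha1, alpha2 = alpha2),
            class = "breath_spec")
}

#' @export
print.breath_spec <- function(x, ...) {
  cat(sprintf(paste0("<breath_spec> T_in = %g s, T_ex = %g s, ",
                     "sum(V0) = %g l, sum(VT) = %g l, alpha1 = %g, alpha2 = %g\n"),
              x$T_in, x$T_ex, sum(x$V0), sum(x$VT), x$alpha1, x$alpha2))
  invisible(x)
}

check_model_spec <- function(model, spec) {
  if (length(spec$V0) != model$m)
    stop("model has ", model$m, " compartments but spec boundary vectors have length ",
         length(spec$V0))
  invisible(TRUE)
}
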