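#' Built-in study fixtures and random model generator
#'
#' `lung_fixture()` builds the lung model plus breath specification used
#' throughout the package's examples and validation runs.
#'
#' The `"two_compartment"` fixture is a one-generation (two-compartment) lung
#' with identical compartments. Compliance, timing and weights are the
#' published spontaneous-breathing-at-rest values: inspiratory curve
#' `a1 = 0.018, b1 = 0.0233, a2 = 0.025, a3 = 0.2532, b3 = -0.01,
#' x1 = 0.3, x2 = 0.48` and expiratory curve `a1 = 0.02, b1 = 0.078,
#' a2 = 0.038, a3 = 0.1025, b3 = -0.15, x1 = 0.23, x2 = 0.43` (l/cmH2O and
#' l), `T_in = 2` s, `T_ex = 3` s, `alpha1 = 2.0`, `alpha2 = 0.1`, total
#' end-expiratory volume `0.2` l and total tidal volume `1.2` l split equally
#' across compartments. Published sources give airway resistance only up to a
#' generation pattern and an expiratory/inspiratory factor of 2.5; the
#' defaults here are a root resistance of 1.0 cmH2O s/l, `0.5 * 2^j` per
#' airway in generation `j >= 1`, and `R_ex = 2.5 * R_in`, all overridable.
#'
#' `"four_compartment"` is the same with two generations (four identical
#' compartments, per-compartment boundary volumes re-split equally).
#'
#' `"random"` draws a valid model of depth `n` with log-uniform resistances
#' and perturbed compliance parameters (still `b1 > 0`, `b3 < 0`,
#' `0 < x1 < x2 <= v_cap`), reproducible from `seed`.
#'
#' @param name `"two_compartment"`, `"four_compartment"` or `"random"`.
#' @param seed integer seed, used only by `"random"`.
#' @param overrides named list overriding any of `T_in`, `T_ex`, `alpha1`,
#'   `alpha2`, `V0`, `VT` (vectors or totals to split), `root_resistance`,
#'   `ex_factor`, `beta_smooth`, `n` (random only).
#' @return a list with elements `model` ([lung_model()]), `spec`
#'   ([breath_spec()]) and `name`.
#' @examples
#' fx <- lung_fixture("two_compartment")
#' fx$model
#' fx$spec
#' @export
lung_fixture <- function(name = c("two_compartment", "four_compartment", "random"),
                         seed = 1L, overrides = list()) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown fixture '", name[1],
         "'; available: two_compartment, four_compartment, random"))
  ov <- overrides
  beta <- ov$beta_smooth %||% 30

  published_curves <- function(beta) list(
    inspiration = compliance_curve(a1 = 0.018, b1 = 0.0233, a2 = 0.025,
                                   a3 = 0.2532, b3 = -0.01,
                                   x1 = 0.3, x2 = 0.48, v_cap = 0.6,
                                   beta_smooth = beta, phase = "inspiration"),
    expiration = compliance_curve(a1 = 0.02, b1 = 0.078, a2 = 0.038,
                                  a3 = 0.1025, b3 = -0.15,
                                  x1 = 0.23, x2 = 0.43, v_cap = 0.6,
                                  beta_smooth = beta, phase = "expiration"))

  default_tree <- function(n, root) {
    res <- c(list(root), lapply(seq_len(n), function(j) rep(0.5 * 2^j, 2^j)))
    airway_tree(n, res[seq_len(n + 1L)])
  }

  if (name %in% c("two_compartment", "four_compartment")) {
    n <- if (name == "two_compartment") 1L else 2L
    m <- 2^n
    root <- ov$root_resistance %||% 1.0
    ex_factor <- ov$ex_factor %||% 2.5
    tree_in <- default_tree(n, root)
    tree_ex <- scale_tree(tree_in, ex_factor)
    curves <- suppressWarnings(published_curves(beta)) # inspiratory x2 jump is known
    model <- lung_model(tree_in, tree_ex,
                        compliance_in = list(curves$inspiration),
                        compliance_ex = list(curves$expiration))
    V0 <- ov$V0 %||% rep(0.2 / m, m)
    VT <- ov$VT %||% rep(1.2 / m, m)
    if (length(V0) == 1L) V0 <- rep(V0 / m, m)
    if (length(VT) == 1L) VT <- rep(VT / m, m)
    spec <- breath_spec(T_in = ov$T_in %||% 2, T_ex = ov$T_ex %||% 3,
                        V0 = V0, VT = VT,
                        alpha1 = ov$alpha1 %||% 2.0,
                        alpha2 = ov$alpha2 %||% 0.1)
  } else {
    n <- ov$n %||% 1L
    m <- 2^n
    rs <- .fixture_rng(seed)
    rand_tree <- function() {
      res <- lapply(0:n, function(j) exp(rs$runif(2^j, log(0.3), log(3))))
      airway_tree(n, res)
    }
    rand_curve <- function(phase) {
      a2 <- rs$runif(1, 0.02, 0.05)
      b1 <- rs$runif(1, 0.02, 0.1)
      a1 <- rs$runif(1, 0.3, 0.9) * a2
      b3 <- -rs$runif(1, 0.1, 0.3)
      x1 <- (a2 - a1) / b1
      x2 <- x1 + rs$runif(1, 0.1, 0.25)
      a3 <- a2 - b3 * x2
      compliance_curve(a1, b1, a2, a3, b3, x1 = x1, x2 = x2,
                       v_cap = x2 + rs$runif(1, 0.1, 0.3),
                       beta_smooth = beta, phase = phase)
    }
    model <- lung_model(rand_tree(), rand_tree(),
                        compliance_in = lapply(seq_len(m), function(i)
                          rand_curve("inspiration")),
                        compliance_ex = lapply(seq_len(m), function(i)
                          rand_curve("expiration")))
    spec <- breath_spec(T_in = ov$T_in %||% 2, T_ex = ov$T_ex %||% 3,
                        V0 = ov$V0 %||% rep(0.1, m),
                        VT = ov$VT %||% rep(0.25, m),
                        alpha1 = ov$alpha1 %||% 2.0,
                        alpha2 = ov$alpha2 %||% 0.1)
  }
  list(model = model, spec = spec, name = name)
}

# local RNG stream that does not disturb the global .Random.seed
.fixture_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm))
}
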