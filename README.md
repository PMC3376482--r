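# lungflow

Optimal respiratory airflow patterns for a nonlinear multicompartment lung
mechanics model.

## The problem

Mechanical ventilation has to move a prescribed tidal volume in and out of a
lung that is neither homogeneous nor linear: the bronchial tree branches
dichotomously into `2^n` terminal compartments, each compartment's
compliance `c_i(x_i)` (volume per unit distending pressure, l/cmH2O) varies
with its volume, and each airway contributes a resistance (cmH2O·s/l) that
differs between inspiration and expiration. Writing `x(t)` for the vector of
compartmental volumes, the pressure balance during each phase is

    R_in  x' + C_in(x)  x = p_in(t) e        (inspiration)
    R_ex  x' + C_ex(x)  x = p_ex(t) e        (expiration)

where `C(x) = diag(1/c_i(x_i))`, `e` is the all-ones vector, and the
resistance matrices `R = Σ_{j,k} R_{j,k} Z_{j,k} Z_{j,k}'` are assembled
from the tree through 0/1 membership vectors `Z_{j,k}`; they are symmetric
positive definite for any positive resistance table.

`lungflow` computes, by calculus of variations, the airflow patterns that
minimize physiologically motivated costs over a breath with fixed timing
(`T_in`, `T_ex`), end-expiratory volume `V0` and tidal volume `VT`:

* **Inspiration** minimizes volume acceleration plus work of breathing,
  `J_in = ∫ x''ᵀx'' + α₁ p_in eᵀx' dt`. Its Euler–Lagrange equation
  `x⁽⁴⁾ = α₁ R_in x''` is linear and independent of compliance; the optimum
  is the closed form `x(t) = d₁ + d₂t + exp(At) d₃ + exp(−At) d₄` with
  `A = √α₁ · R_in^{1/2}` (solved mode-by-mode in the eigenbasis of `R_in`),
  degenerating to a cubic when `α₁ = 0`.
* **Expiration** minimizes volume acceleration plus the integral squared
  driving pressure (a proxy for the oxygen cost of braking expiration),
  `J_ex = ∫ x''ᵀx'' + α₂ p_ex² eᵀe dt`. Its Euler–Lagrange equation is a
  nonlinear fourth-order two-point boundary-value problem in `C_ex(x)` and
  `C_ex'(x)`, solved here by 3-stage Lobatto IIIA (Simpson) collocation with
  damped Newton iterations, adaptive mesh refinement and continuation in
  `α₂`.

The package also forward-simulates either phase under arbitrary ventilator
waveforms (`deSolve`), reconstructs the driving pressure a trajectory
implies, evaluates and compares the performance functionals, iterates
breathing cycles to their limit cycle, and cross-checks both optimal
solvers against an independent direct-transcription minimizer
(sparse Gauss–Newton / L-BFGS on a finite-difference discretization).

## Worked example

```r
library(lungflow)

fx <- lung_fixture("two_compartment")   # published two-compartment model
fx$spec
#> <breath_spec> T_in = 2 s, T_ex = 3 s, sum(V0) = 0.2 l, sum(VT) = 1.2 l, alpha1 = 2, alpha2 = 0.1

cyc <- run_cycle(fx$model, fx$spec)
cyc
#> <breath_cycle> T_in = 2 s, T_ex = 3 s, 2 compartment(s)
#>   J_in = 42.663, J_ex = 568.11, J_total = 610.77

glance(cyc)[, c("J_total", "end_inspiratory_total_l", "tidal_excursion_l")]
#> # A tibble: 1 × 3
#>   J_total end_inspiratory_total_l tidal_excursion_l
#>     <dbl>                   <dbl>             <dbl>
#> 1    611.                    1.40              1.20
```

`J_in` and `J_ex` are the attained phase criteria (acceleration plus work,
and acceleration plus squared pressure); the summed volume rises from 0.2 l
to exactly 1.4 l at end-inspiration and the solved tidal excursion is
exactly the prescribed 1.2 l. `tidy(cyc)` returns the full trajectory as a
long tibble and `ggplot2::autoplot(cyc)` plots it; note that with the
published compliance parameters the optimal expiration transiently
undershoots the end-expiratory level before returning to it (see the
methods vignette for why that is a property of the stated optimization
problem, not a solver artifact).

Compare against the standard nonoptimal reference ventilation
(`p_in = 20t + 5` cmH2O, passive expiration at 0 cmH2O):

```r
pr  <- reference_pressures(2, 3)
ins <- simulate_phase(fx$model, "inspiration", pr$inspiration, x0 = fx$spec$V0)
ex  <- simulate_phase(fx$model, "expiration",  pr$expiration,
                      x0 = ins$x[nrow(ins$x), ])
compare_performance(cyc, list(inspiration = ins, expiration = ex),
                    fx$model, fx$spec)$summary
#> # A tibble: 2 × 4
#>   label      J_in     J_ex  J_total
#>   <chr>     <dbl>    <dbl>    <dbl>
#> 1 optimal    42.7 5.68e+ 2 6.11e+ 2
#> 2 reference 103.  1.87e+18 1.87e+18
```

A thin command-line wrapper over these functions is installed at
`inst/cli/lungflow.R` (subcommands `fixture`, `solve`, `simulate`,
`pressure`, `compare`, `limit-cycle`, `validate`).

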