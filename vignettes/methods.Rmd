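---
title: "Models and numerical methods in lungflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in lungflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model, the numerical methods, and the design
decisions behind `lungflow`, at the level of detail a maintainer or a
reviewer of the numerics would want. Nothing here reports a number that the
test suite or `scripts/acceptance.R` does not itself compute.

## The mechanical model

The lung is a dichotomous airway tree of depth `n`: one root airway splits
into two at every generation, ending in `m = 2^n` terminal compartments.
Compartment volumes are the state vector `x(t)` (litres). Two ingredients
define the mechanics:

* **Airway resistances** `R[j][k]` (cmH2O·s/l), one per airway, per phase
  (expiratory resistances exceed inspiratory ones). The pressure balance
  couples compartments through shared ancestors, which is captured by the
  matrix `R = Σ R[j][k] Z[j,k] Z[j,k]ᵀ` where `Z[j,k]` flags the
  compartments ventilated through airway `(j, k)`. Entry `(i, i')` of `R`
  is the summed resistance of the path shared by compartments `i` and
  `i'`; the matrix is symmetric positive definite whenever all resistances
  are positive, which keeps the dynamics well posed. The test suite checks
  the assembly against a brute-force shared-ancestor construction for all
  depths up to 4.
* **Volume-dependent compliance** `c_i(x_i)` (l/cmH2O), a three-segment
  piecewise-linear curve: a rising limb `a1 + b1 x` (recruitment at low
  volume, `b1 > 0`), a plateau `a2`, and a falling limb `a3 + b3 x`
  (overdistension, `b3 < 0`), with breakpoints `x1 < x2`. Because the
  expiratory Euler–Lagrange equation needs the derivative of `1/c`, all
  solvers use a smooth sigmoid-difference approximation
  `c(x) ≈ a2 (S[a,b](x) − S[c,d](x))` with sharpness `beta_smooth`
  (1/l; default 30), whose anchors are derived from the segment
  parameters. The piecewise form is retained for inspection
  (`mode = "piecewise"`), with left-closed segments as the tie-break at
  breakpoints.

Phase dynamics under an applied airway-opening pressure `p(t)` (cmH2O,
gauge):

```
R x'(t) + C(x) x(t) = p(t) e,     C(x) = diag(1/c_i(x_i)).
```

### Extensions and guards

The compliance curve is only stated on `[0, v_cap]`. Trajectories can leave
that range (the published two-compartment experiment drives compartments to
`V0_i + VT_i = 0.7` l against a curve stated up to 0.6 l), so the falling
limb is extended affinely in piecewise mode and the sigmoid extension is
used in smoothed mode, with compliance floored at `1e-6` l/cmH2O so `1/c`
stays finite. Crossing the stated domain raises a warning, not an error.

Two published parameter quirks are preserved deliberately:

* the inspiratory falling limb (`a3 = 0.2532`, `b3 = −0.01`) does not meet
  the plateau at `x2 = 0.48` (0.2484 vs 0.025). Parameters are stored as
  printed; the constructor warns when the jump exceeds 1% of the plateau.
  In smoothed mode this limb is irrelevant at physiological volumes
  because its sigmoid anchors sit near 23–25 l.
* the expiratory curve is continuous at its upper breakpoint but off by
  0.16% at the lower one; no correction is applied.

## Optimal inspiration

The inspiratory criterion is volume acceleration plus work of breathing,
`J_in = ∫ x''ᵀx'' + α₁ p_in eᵀx' dt` (`α₁` in l/(s³·cmH2O), default 2.0),
with clamped boundary conditions `x(0) = V0`, `x(T_in) = V0 + VT`,
`x'(0) = x'(T_in) = 0`. Eliminating `p_in` through the state equation and
taking variations yields the linear system `x⁽⁴⁾ = α₁ R_in x''` — the
optimal inspiratory pattern is independent of compliance, and is solved in
closed form:

* `α₁ > 0`: `x(t) = d₁ + d₂ t + exp(At) d₃ + exp(−At) d₄`, with
  `A = √α₁ · R_in^{1/2}` (the unique symmetric positive-definite square
  root, via eigendecomposition). The boundary system is solved per
  eigenmode of `R_in` with a `cosh`/`sinh` parametrization centred at
  `T_in/2`, so no large exponentials are formed regardless of `α₁`.
* `α₁ = 0`: the cubic `d₁ = V0`, `d₂ = 0`, `d₃ = 3VT/T_in²`,
  `d₄ = −2VT/T_in³`.

The exponent convention (`√α₁` times the matrix square root, not a square
root of `α₁ R_in` applied otherwise) is fixed by substituting back into the
fourth-order equation; the residual test pins it. The two branches agree in
the `α₁ → 0⁺` limit (checked at `α₁ = 1e−8`).

## Optimal expiration

The expiratory criterion replaces mechanical work with the integral squared
driving pressure, `J_ex = ∫ x''ᵀx'' + α₂ p_ex² eᵀe dt` (`α₂` in
l²/(s⁴·cmH2O), default 0.1), because expiratory muscle activity performs
negative work and correlates with squared pressure rather than work. After
eliminating `p_ex`, the Euler–Lagrange equation is the nonlinear
fourth-order system

```
x⁽⁴⁾ − α₂ R² x'' + α₂ C(x)² x
  + α₂ [ C R x' − R C x' + X C' R x' − R C' X x' + X C' C x ] = 0
```

with `X = diag(x_i)` and `C' = diag(d(1/c_i)/dx_i)` (analytic, from the
smoothed compliance). For `α₂ = 0` the unique minimizer is the Hermite
cubic through the boundary data.

### Collocation solver

The equation is reduced to a first-order system in
`y = (x, x', x'', x''')` (dimension `4m`) and discretized by the 3-stage
Lobatto IIIA (Simpson) scheme — the same family as MATLAB's `bvp4c` — on a
mesh of `n_mesh` nodes (default 1501). The resulting sparse
almost-block-diagonal nonlinear system (unknowns: all nodal states;
equations: `2m` boundary conditions at each end plus one Simpson residual
per interval) is solved by damped Newton iterations: per-node Jacobians of
the right-hand side by central differences, interval blocks assembled
analytically from them, sparse LU through the Matrix package, and step
halving until the residual norm decreases. The initial guess is the
`α₂ = 0` Hermite cubic; if the direct solve stalls, continuation in `α₂`
(four stages from 0) is attempted. Newton tolerance is `1e-8` on the max
collocation residual.

### Mesh adaptation and the residual diagnostic

The published parameters produce severe layers: at the start of expiration
the compartments sit at 0.7 l, where the smoothed expiratory compliance has
decayed to about 0.002 l/cmH2O, so the elastic term is huge and the
solution moves on a fast time scale; a second, milder layer appears where
the trajectory crosses the steep part of the curve. The solver therefore
uses a sine-graded base mesh (endpoint density `1/(1−grading)` times the
interior, default grading 0.95) and up to `adapt` rounds (default 6) of
residual-driven re-equidistribution: the Euler–Lagrange residual is
measured at every node by differentiating the stored third derivative with
non-uniform 5-point stencils and comparing against the fourth derivative
the equation implies; local spacing is shrunk as (residual/target)^(1/4)
(the scheme is 4th order), the profile smoothed, the mesh regrown by ~30%
and the solve warm-started by quintic Hermite interpolation. On the
published two-compartment model this reaches a max residual near `1e-5` in
a few thousand nodes. The residual so computed is an honest independent
diagnostic: it recomputes the fourth derivative from the solution rather
than reusing the equation.

The returned trajectory is resampled onto a uniform grid (default 401
nodes) by quintic Hermite interpolation so that Simpson-based functional
evaluation applies directly; the raw collocation states remain available.

### The undershoot

With the published compliance parameters, weights and the package's default
resistances, the optimal expiration is *not* monotone: the summed volume
dips below the end-expiratory level (to about −0.02 l) before returning to
0.2 l, and per-compartment volumes transiently go slightly negative. Three
independent computations agree on this — the collocation solver, the
direct-transcription minimizer, and the exact solution of the
constant-compliance single-compartment case — so it is a property of the
stated optimization problem, not a numerical artifact. The mechanism is
visible in the linear special case `x⁽⁴⁾ − α₂R²x'' + α₂C²x = 0`: with
plateau compliance 0.038 l/cmH2O the problem sits deep in the oscillatory
regime (`α₂ ≪ 4C²/R⁴` for any physiological resistance), and because the
squared-pressure term dominates (`(α₂C²)^{1/4} T_ex ≫ 1`), the minimizer
hugs the pressure-free passive decay — which relaxes towards zero volume,
not towards `V0` — and only climbs back to `V0` near the end of the phase.
The start-of-expiration pressure spike (~290 cmH2O implied by 0.7 l against
the extended expiratory curve) sharpens the effect but does not cause it.
`classify_linear_regime()` exposes the four-family classification of the
linear case by comparing `α₂` with `4C²/R⁴`.

Accounts of this model elsewhere describe the expiration as monotonically
decreasing; under the parameter set as printed we find that claim does not
hold, and the package documents rather than hides the discrepancy (the
corresponding end-to-end check is intentionally kept failing, with this
explanation). The zero-weight optimum is provably monotone and is tested as
such.

### The published cubic coefficient set

A published closed-form coefficient set exists for the `α₂ = 0` expiratory
cubic. Substituted into the cubic on the global clock it reproduces the
start volume and both zero-flow conditions exactly but misses the
end-volume condition by a wide margin (0.63 l per compartment for the
two-compartment timing), so it cannot be the boundary-value solution;
`solve_expiration()` uses the Hermite cubic, and
`expiration_reference_cubic()` preserves the published set verbatim with a
per-condition mismatch report.

## Forward simulation, pressures, functionals, cycles

* `simulate_phase()` integrates `x' = R⁻¹(p(t)e − C(x)x)` with
  `deSolve::lsoda` (rtol `1e-8`, atol `1e-10`; tight because trajectories
  feed derivative-based diagnostics). Flows are recovered exactly from the
  state equation and accelerations analytically from its time derivative,
  avoiding numerical differentiation noise.
* `reconstruct_pressure()` inverts the pressure balance row by row. For
  heterogeneous compartments an optimal trajectory need not be realizable
  by a single airway-opening pressure, so the consensus (mean across
  compartments) is always reported together with the spread (max deviation
  from consensus); a large spread flags non-realizability. For the built-in
  identical-compartment fixtures the spread is at rounding level.
* Functionals use composite Simpson on the uniform trajectory grid (odd
  node counts throughout). The inspiratory compliance term
  `∫ xᵀC(x)x' dt` is a path-independent potential given fixed endpoints,
  which is why inspiratory optimality is insensitive to it.
* `run_cycle()` chains the two optima with shared boundary data, making
  the cycle periodic by construction. `limit_cycle_analysis()` iterates
  forward-simulated cycles to a fixed point (default tolerance `1e-6` l,
  cap 50 cycles). Under the reference waveforms (`20t + 5`, then 0) the
  model lung empties almost completely during the 3 s passive phase (time
  constant `R·c ≈ 0.2` s), so the fixed point is near zero volume and
  convergence takes two cycles.

## The independent oracle

`direct_minimize()` validates both solvers by brute force: nodal volumes
are decision variables, flows and accelerations come from sparse
finite-difference operators (4th order by default; order-matched one-sided
closures at the ends), boundary volumes are clamped, and the zero-flow
conditions are enforced by eliminating the nodes adjacent to each boundary
through the one-sided first-derivative stencils. Three numerical choices
matter and were each adopted after the naive alternative failed measurably:

* **Quadrature weights are non-alternating** (Gregory-corrected trapezoid
  on uniform grids, trapezoid on graded ones). Simpson's alternating
  weights let grid-frequency modes shift cost onto low-weight nodes and
  lower the discrete functional by ~10% without changing the trajectory
  visibly.
* **Expiration is minimized by Levenberg-damped Gauss–Newton.** The
  expiratory integrand is exactly a sum of squares
  (`|x''|² + α₂|R x' + C(x)x|²`), so the sparse residual Jacobian is
  available; quasi-Newton methods stall on the `O(N⁴)` conditioning of the
  fourth-order operator at the grid sizes the layers demand, while
  Gauss–Newton converges in a handful of iterations. The `α₁ = 0`
  inspiratory case shares this structure and route; general inspiration
  (whose work term is not a square) uses L-BFGS-B with the fully analytic
  gradient (validated against central differences in the tests).
* **A graded grid for expiration.** On uniform grids the discrete optimum
  develops a numerical boundary layer at the clamped start that
  under-resolves the compliance wall and sits ~3% below the continuum
  optimum in functional value no matter how large N; the same sine grading
  as the collocation mesh removes the effect.

With these choices the transcription minimizer agrees with the collocation
solution to ~4e-5 l in sup-norm and well under 0.5% in functional value on
the published model, and recovers both zero-weight cubics. A
manufactured-solution check (trigonometric trajectories with exact
derivatives) validates the Euler–Lagrange operator itself to `1e-6`.

## Built-in models and their defaults

`lung_fixture()` provides the study conditions:

* `"two_compartment"` (`n = 1`): the published compliance parameters for
  both phases, `T_in = 2` s, `T_ex = 3` s, `α₁ = 2.0`, `α₂ = 0.1`,
  `beta_smooth = 30`, total end-expiratory volume 0.2 l and total tidal
  volume 1.2 l. Only totals are published, so volumes are split equally
  across compartments (0.1/0.6 l each); the split is overridable.
  Published sources give airway resistance only as typical per-generation
  values plus an expiratory/inspiratory factor of 2.5; the defaults are a
  root resistance of 1.0 cmH2O·s/l and `0.5·2^j` per airway of generation
  `j ≥ 1` (resistance rising as airways narrow), `R_ex = 2.5 R_in`, all
  overridable. No numerical conclusion in the tests depends on the
  absolute resistance scale except through the dynamics it implies.
* `"four_compartment"` (`n = 2`): same compartment parameters, volumes
  re-split four ways.
* `"random"`: seed-deterministic valid models (log-uniform resistances,
  perturbed but sign-correct compliance segments) for property tests; the
  generator does not disturb the session RNG.

What these fixtures emulate is the mechanics of a sedated, passive patient
on a ventilator at rest, with identical compartments; what they do not
emulate is inter-compartment heterogeneity (the published experiments use
identical compartments, so pressure-spread diagnostics are exercised only
structurally), volume-dependent resistance, gas exchange, or active
expiratory muscle pressure. Passing tests therefore validate the
mathematics and numerics, not physiological realism of any particular
parameter set.

## Problem sizes and tolerances used in validation

The test suite runs the two-compartment cycle with the default solver
settings (collocation to ~7000 adapted nodes for the residual check, 401
output nodes), oracle grids of 81–1281 nodes (graded 0.98 for expiration),
100 random admissible perturbations per phase for the optimality
spot-check, 200 random trees for positive-definiteness, and exhaustive
shared-ancestor comparisons for depths 0–4. Boundary conditions are
verified to `1e-7` l (l/s), the inspiratory Euler–Lagrange residual to
`1e-8`, the expiratory one to `1e-5`, and oracle agreement to `1e-3` l /
0.5%.

## Known limitations

* The expiratory solver targets the Euler–Lagrange stationarity system; it
  does not certify global optimality (the direct-transcription agreement is
  the evidence that the computed stationary point is the minimizer).
* Trajectories that leave `[0, v_cap]` rely on the documented compliance
  extension; results there inherit the extension's arbitrariness, which is
  exactly the regime the published two-compartment parameters enter.
* The cycle is periodic by construction of the boundary conditions, not by
  proof that repeated optimal cycles are a stable limit cycle; the
  limit-cycle machinery applies to forward-simulated (fixed-waveform)
  breathing.
* Asymmetric (non-dichotomous) trees and volume-dependent resistance are
  out of scope.
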