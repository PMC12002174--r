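---
title: "Ecology meets evolutionary games: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecology meets evolutionary games: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvgames)
```

## The two frameworks and the bridge between them

`lvgames` studies `m` interacting types whose abundances `n_i` follow the
generalized Lotka–Volterra (LV) equations

$$\dot n_i = n_i\Big(r_i + \sum_j a_{ij} n_j\Big),$$

with `a_ij` the per-capita effect of type `j` on type `i` (row = affected,
column = acting — every file format written by the package records this
orientation explicitly, because transposed matrices are the most common
source of silent errors in this literature) and `r_i` the intrinsic growth
rate of type `i` when rare and free of all interactions.

Changing variables to frequencies `x_i = n_i/N`, `N = Σ n_i`, gives the
exactly equivalent coupled system integrated by `integrate_coupled()`:

$$\dot x_i = x_i\big[(r_i - \bar r) + N\,(f_i - \bar f)\big], \qquad
  \dot N = N\,(\bar r + N \bar f),$$

with `f_i = Σ_j a_ij x_j`, `f̄ = Σ x_i f_i`, `r̄ = Σ x_i r_i`. Two things
are immediate from the bracket:

1. If all `r_i` are equal, the growth-rate term vanishes and the frequency
   equation is the replicator equation of evolutionary game theory up to a
   rescaling of time by the positive factor `N`. `check_equivalence()`
   verifies this numerically: it integrates the LV system together with the
   rescaled clock `τ` (with `dτ/dt = N`), samples the replicator trajectory
   exactly at `τ(t)`, and reports the maximum pointwise deviation. We
   integrate `τ` as an extra state variable rather than interpolating a
   stored `N(t)`, so the clock carries the same accuracy as the trajectory
   itself and no interpolation error enters the comparison.
2. If the `r_i` differ (and the system is bounded, so `N` neither explodes
   nor makes the `1/N`-term negligible), the frequency dynamics is not
   autonomous: no replicator equation reproduces it. The deviation reported
   by `check_equivalence()` is then order one — on the Prisoner's Dilemma
   fixture with `r = (2, 1)` the replicator predicts cooperator extinction
   while the LV frequency converges to 3/8.

## The two-type outcome classification

For two types we require self-limitation (`a11, a22 < 0`). The classical
product condition `a12·a21 < a11·a22` rules out runaway mutualistic
feedback; `is_bounded()` applies it whenever the cross-effects could fuel
growth, but deliberately admits purely competitive matrices that violate
it, because negative cross-effects cannot cause divergence — each abundance
is capped by its own logistic envelope. This choice is what makes the
bistable (coordination-game) region classifiable at all: every matrix with
both off-diagonals below the corresponding diagonals has
`a12·a21 > a11·a22`, yet its dynamics is perfectly bounded. A `strict`
argument restores the literal product inequality for users who want the
sufficient condition only.

`classify_outcome()` rests on mutual invasibility. Type 2 grows at type 1's
monoculture equilibrium `n̂₁ = −r1/a11` iff `r2 + a21·n̂₁ > 0`, which is
algebraically `a21 > a11·r2/r1`; symmetrically type 1 invades iff
`a12 > a22·r1/r2`. Both inequalities holding means coexistence, neither
means bistability, exactly one means dominance — and the dominant type is
the successful invader, which is how the package resolves the direction of
dominance. With equal rates the thresholds reduce to `a11` and `a22` and
the classification collapses onto the familiar game quadrants
(`classify_game()`); with unequal positive rates the thresholds move to
`a11·r2/r1` and `a22·r1/r2` (`classification_boundaries()`). When only one
rate is positive the other type cannot stand alone and the verdict is
decided by a single invasion condition; when neither is positive both types
decline (`EXTINCTION_BOTH`). The special value `r_i = 0` is grouped with
the nonpositive branch — a type with zero intrinsic growth decays as
`ṅ = a_ii n² < 0` on its own — and flagged degenerate.

Comparisons that land within `1e-9` of a threshold are flagged
`DEGENERATE` rather than silently classified: these boundaries have
measure zero, the underlying theory does not define them, and any verdict
there would reflect rounding rather than dynamics.

`critical_r1()` returns the exact dominance-to-coexistence threshold
`r2·a12/a22` for matrices in which type 1 loses at equal rates
(`a12 < a22 < 0`). Its `"bisection"` method finds the same point by a
completely different route — expanding a bracket and bisecting on the
appearance of a feasible, linearly stable interior equilibrium from
`fixed_points()` — which is used as an independent cross-check.

`achievable_outcomes()` answers the converse question: which outcomes can
growth rates produce for a fixed matrix? Working through the sign regimes:
dominance of either type is always reachable (drive the other type's
intrinsic rate sufficiently negative), joint extinction is always reachable,
coexistence is reachable exactly when `a12·a21 < a11·a22`, and bistability
exactly when both cross-effects are negative with `a12·a21 > a11·a22`.
Every witness pair `(r1, r2)` the function returns is verified through
`classify_outcome()` before being reported.

## The simulation oracle

`simulate_outcome()` is the package's independent check on the analytic
classifier: long-run LV integration from four initial conditions (each
boundary equilibrium perturbed by an inoculum of `1e-4`, plus two interior
states). Its verdict rule deserves a note, because the naive version —
integrate for a fixed horizon and threshold the final abundances — fails in
two mirror-image ways near classification boundaries: a slowly dying type
can still sit above any fixed floor at the horizon, and a genuinely
coexisting type whose interior equilibrium component is tiny (which happens
precisely when an invasion margin is small) can sit below it. The oracle
therefore integrates in geometrically growing time chunks and stops only
when the state has verifiably converged onto one of the enumerated fixed
points — within a radius set well below the minimum separation between
fixed points, with the derivative below `1e-10`. The verdict is the support
of the reached equilibrium, so no abundance threshold enters it. Systems
within `1e-3` of a classification threshold are excluded from
oracle-agreement tests; for everything else the classifier and the oracle
agree on 200/200 seeded random systems.

## Integration defaults

All integrators use `deSolve::lsoda` with relative tolerance `1e-10` and
absolute tolerance `1e-12`. The defaults are deliberately tight: the
symmetric Rock-Paper-Scissors community has a neutrally stable interior
(closed orbits), and both the closed-orbit return test and the conservation
of `x_R·x_P·x_S` drift visibly under looser tolerances.

Two numerical safeguards are worth knowing about because they are easy to
get wrong in this model class:

* **Structural zeros.** A type with `n_i(0) = 0` can never become positive
  in exact LV dynamics, but a solver carries O(atol) dust in every
  component, and in a cyclic community that dust is amplified exponentially
  by any positive invasion rate — an absent Rock "invades" a Scissors
  resident out of numerical nothing. `integrate_lv()` therefore integrates
  only the subsystem of initially present types; absent types are exactly
  zero by construction.
* **Simplex drift.** The replicator vector field leaves the simplex
  invariant but not attracting: once a frequency decays to ~`1e-10`, any
  error in `Σx` is amplified and the state collapses off the simplex. The
  replicator and coupled integrators evaluate fitness terms on the
  normalized state, which makes `Σx` an exact invariant of the extended
  field; the residual defect (reported in `diagnostics`) stays below
  `1e-9` over `t = 1000` on all fixtures.

Abundances below the extinction floor (`1e-9` by default) are clamped to
zero only at the end of an integration, never mid-step: mid-step clamping
distorts the near-boundary excursions of heteroclinic-like cycles. Runs
whose abundances exceed `1e6` are truncated and flagged `unbounded` rather
than raising an error, so strong-mutualism parameter sets are diagnosed,
not crashed on.

## Fixed points, stability, invasion

`fixed_points()` solves the linear system `r + A n = 0` restricted to every
support subset (capped at 10 types; enumeration is `2^m`), keeps strictly
positive solutions, and labels stability from the eigenvalues of the full
Jacobian `J_ik = δ_ik(r_i + Σ_j a_ij n_j) + n_i a_ik` with tolerance
`1e-8` on real parts: `STABLE` below `−1e-8`, `NEUTRAL` within `±1e-8` of
zero, `SADDLE`/`UNSTABLE` otherwise. The tolerance is chosen so the
symmetric cyclic community's interior — one contracting direction plus a
conjugate pair with real part zero up to rounding — is labeled `NEUTRAL`
rather than marginally stable or unstable. Neutrality is independently
corroborated by the conserved product `x_R·x_P·x_S` along replicator
orbits (relative drift below `1e-6` over `t = 100`), so both the spectral
and the conserved-quantity characterizations are tested.

`invasion_fitness()` is the rare-type growth rate
`r_inv + Σ_j a_inv,j n̂_j` at a resident equilibrium — positive means
deterministic invasion from any low inoculum. Its sign is algebraically
identical to the classifier's inequalities, and the suite asserts that
identity on 200 random systems.

## Stepwise assembly

`assemble()` implements the rare-migrant protocol: one type at a time
arrives at inoculum `1e-6` into a fully relaxed resident community
(timescale separation is enforced — no arrival into a still-relaxing
state), the system relaxes for up to 500 time units (doubled once on
demand), and types below the floor are pruned. Invasion fitness is
recorded against fixed-point residents; against a cycling resident it is
`NA` and the simulation itself decides the invasion, since the equilibrium
formula presumes a steady resident. Relaxation regimes are `FIXED_POINT`
(derivative sup-norm below `1e-8` sustained over 5 time units), `CYCLE`
(non-decaying oscillation over the trailing 100-unit window with all
supported types above the floor), `EXTINCT`, or `INDETERMINATE` if neither
fits after the retry.

On the cyclic fixtures (`α = 1.3`): with equal growth rates every one of
the six introduction orders ends with a single surviving type — each
arrival simply replaces the strategy it beats, so the full cycle can never
be assembled. With `r_R = 2.5` the R+P pair becomes mutually invasible
(`0.3 > −1/2.5` and `−2.3 > −2.5`), forming a two-type stepping stone that
Scissors then invades (fitness `1 − 2.3·(20/169) + 0.3·(175/169) ≈ 1.04`),
and the full three-type community assembles. A point worth stating
plainly: at these parameters the assembled three-type state is a linearly
*stable* focus (eigenvalues `−1.19` and `−0.154 ± iω`), so the community
converges to steady three-type coexistence through damped oscillations —
"cyclic" describes the dominance structure of the interaction network
(R beats S beats P beats R), not a sustained limit cycle. Sustained cycles
do occur in the equal-rate community, whose neutral interior supports
closed orbits; that is where the `CYCLE` regime detector is exercised.
Assembly verdicts are insensitive to the inoculum across `1e-4`–`1e-8`.

## The random-system generator

`sample_bounded_system()` draws diagonal entries uniformly from
`[−5, −0.5]` and off-diagonals from `[−5, 5]`, rejecting draws violating
`a12·a21 < a11·a22`, and returns types in canonical order (`a11 ≥ a22`).
The ranges span all three ecological sign quadrants (mutualism,
exploitation, competition) at interaction strengths comparable to the
worked examples; the theory itself places no bound on entry magnitudes, so
the ranges are a repository choice made once. Note that the strict product
inequality means sampled systems never land in the bistable region — the
bistability branch of the classifier is exercised by explicit competitive
matrices instead. Sampling is seed-deterministic and restores the caller's
RNG state.

What the generated ensembles emulate — and what they do not: random bounded
pairwise interactions with growth rates of moderate dynamic range
(`0.2`–`3`), no correlation structure between matrix entries, no
higher-order interactions, no demographic noise, no spatial structure.
Passing the oracle-agreement tests therefore certifies the analytic
classification for well-mixed deterministic pairwise systems, and nothing
beyond that.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use: 200 random systems for the
oracle-agreement and sign-regime ensembles (1000 for the sampler-constraint
property), equivalence comparisons at 400 points over `t ∈ [0, 100]`,
replicator conservation over `t = 100` at 4000 points, and exhaustive
6-order assembly searches for the three-type pools. These sizes give
stable verdicts (the ensemble results are identical across seeds) while
keeping a full run in the tens of seconds.

## Known limitations

* The analytic classification is closed-form for two types only; larger
  communities are analyzed through `fixed_points()`, invasion fitness and
  simulation/assembly.
* No stochasticity: invasion at positive fitness is deterministic, whereas
  in finite populations rare invaders are frequently lost by drift.
* The extinction floor is a modeling device, not a population size; results
  that hinge on abundances near the floor (deep heteroclinic excursions)
  are resolved only down to the integrator's absolute tolerance.
* The frequency-dependent variant `integrate_lv_freqdep()` has no density
  self-limitation, so its total abundance grows or decays exponentially
  once frequencies settle; it is intended for studying frequency outcomes,
  not long-run abundances.
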