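# lvgames

Ecology and evolutionary game theory in one framework: generalized
Lotka–Volterra (LV) dynamics for interacting types with **unequal intrinsic
growth rates**, and tools that show exactly when the replicator equation of
evolutionary game theory is — and is not — a valid description of the same
system.

## Who this is for

Theoretical ecologists and evolutionary game theorists working with small
interaction networks: two-strategy social dilemmas (Prisoner's Dilemma,
Hawk–Dove/Snowdrift, Stag-Hunt), two-species ecological pairs (mutualism,
exploitation, competition), and cyclic (Rock-Paper-Scissors) communities.

## The model

Abundances follow the generalized Lotka–Volterra equations

```
dn_i/dt = n_i ( r_i + Σ_j a_ij n_j )
```

where `a_ij` is the per-capita effect of type *j* on type *i* (row =
affected, column = acting) and `r_i` is the intrinsic growth rate of type
*i* when rare and free of interactions. Writing `x_i = n_i / N` with
`N = Σ n_i`, the frequency dynamics is

```
dx_i/dt = x_i [ (r_i − r̄) + N (f_i − f̄) ],    f_i = Σ_j a_ij x_j
```

When all `r_i` are equal the bracket loses its `N`-independent term and
this is the replicator equation `dx_i/dt = x_i (f_i − f̄)` up to a rescaling
of time by the positive factor `N`. When the `r_i` differ, the frequency
dynamics cannot be separated from `N`: **no replicator equation exists**,
and the game-theoretic classification of outcomes loses its meaning.

For two bounded types (`a11, a22 < 0` and no runaway mutualism) the
long-run outcome is decided by two invasion inequalities:

* type 2 invades type 1's monoculture iff `a21 > a11 · r2/r1`
* type 1 invades type 2's monoculture iff `a12 > a22 · r1/r2`

Both ⇒ coexistence; neither ⇒ bistability; exactly one ⇒ dominance of the
invader. With equal rates these reduce to the classical quadrants
(Prisoner's Dilemma / Harmony / coexistence game / coordination game);
with unequal rates the quadrant boundaries move to `a11·r2/r1` and
`a22·r1/r2`, so a growth-rate change alone can turn dominance into
coexistence, bistability, or dominance of the other type.

## Worked example: a Prisoner's Dilemma that is not a dilemma

The matrix `A = [[-3, -5], [1, -4]]` has the Prisoner's Dilemma payoff
ranking `a21 > a11 > a22 > a12`: defectors (type 2) always dominate
cooperators (type 1) when growth rates are equal.

```r
library(lvgames)

sys <- fixture_system("pd_equal")        # the matrix above, r = (1, 1)
classify_outcome(sys)$outcome
#> [1] "DOMINANCE_2"

critical_r1(sys$A, r2 = 1)               # r2 * a12 / a22
#> [1] 1.25
```

Cooperators need a growth-rate advantage of 25% to escape the dilemma.
Give them `r1 = 2` and the two types coexist at the interior equilibrium
`n = (3/17, 5/17)`:

```r
su <- fixture_system("pd_unequal")       # same matrix, r = (2, 1)
classify_outcome(su)$outcome
#> [1] "COEXISTENCE"

fixed_points(su)[[4]]
#> <lv_equilibrium> support {C,D} STABLE
#>         C         D
#> 0.1764706 0.2941176

check_equivalence(su, c(0.1, 0.1), t_end = 100)$max_orbit_deviation
#> [1] 0.375
```

The replicator equation for the same matrix predicts cooperator extinction
(`x1 → 0`); the true frequency converges to `3/8` — a deviation of 0.375,
i.e. the replicator prediction is qualitatively wrong.

## Assembling a cyclic community step by step

With equal growth rates, a Rock-Paper-Scissors community cannot be built
one rare migrant at a time (each arrival simply replaces the resident it
beats); a sufficient growth-rate advantage for one strategy creates a
two-type coexistence stepping stone:

```r
can_assemble(fixture_system("rps_equal"), c("R", "P", "S"))$possible
#> [1] FALSE
rec <- can_assemble(fixture_system("rps_unequal"), c("R", "P", "S"))$record
rec$steps
#>   introduced invasion_fitness      regime support
#> 1          R         2.500000 FIXED_POINT       R
#> 2          P         1.750000 FIXED_POINT     R,P
#> 3          S         1.038462 FIXED_POINT   R,P,S
```

## Command line

A thin CLI is installed at `exec/lvgames`:

```sh
lvgames fixtures pd_equal --out sys.json
lvgames classify sys.json
lvgames equilibria sys.json
lvgames simulate sys.json --dynamics lv --init 0.1,0.1 --t-end 100 --out traj.csv
lvgames assemble sys.json --search R,P,S
lvgames grid sys.json --out grid.csv
```

System files are JSON/YAML/CSV with keys `labels`, `matrix` (row =
affected), `growth_rates`.

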