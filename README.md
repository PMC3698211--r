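# bistacert

Certification tools for bistability in mass-action reaction networks,
built around a nine-species model of the yeast galactose (*GAL*)
regulatory switch.

Cellular decision circuits such as the *GAL* system hold two coexisting
stable steady states — a low- and a high-expression regime — and the
biological claim "this model explains persistent carbon-source memory"
rests on more than finding those two states once. It requires showing
that each state tolerates perturbations of the species concentrations
(a nontrivial domain of attraction), and that the coexistence of both
states survives simultaneous variation of many kinetic parameters. This
package implements that whole argument as checkable computations for any
network with mass-action kinetics, where the right-hand side

```
xdot = N v(x, p),   v_r(x, p) = p_r * prod(reactant concentrations)
```

is at most quadratic in the state (`N` the stoichiometric matrix). The
package is aimed at systems biologists and control engineers analysing
small-to-medium ODE models of regulatory switches.

## What it computes

* **Equilibria** — seeded multistart damped-Newton search, stability from
  the Jacobian spectrum (`find_equilibria`). For the packaged GAL model
  this returns the two published stable states plus the saddle between
  them.
* **Domain-of-attraction certificates** — for the shifted quadratic
  system `zdot = A z + (z'F_i z)_i`, an axis box `S` around a stable
  equilibrium is certified inside its basin if there are `gamma` in
  (0,1) and `M` positive definite with `M >= gamma^2 a_k a_k'` for the
  face normals, `v'Mv <= 1` at the vertices, and
  `gamma (A'M + MA) + M D(v) + D(v)'M < 0` at the vertices (rows of
  `D(z)` are `z'F_i`). At fixed `gamma` these are linear matrix
  inequalities in `M`; feasibility is solved by a built-in barrier
  method and every certificate is re-verified by plain eigenvalue
  checks (`certify_box`, `grow_box`, `verify_box_by_simulation`).
* **Local sensitivity** — forward sensitivity equations coupled to the
  states, normalized coefficients `s_ij = (dx_i/dp_j) p_j / x_i`, and a
  deterministic parameter ranking (`sensitivity_integrate`,
  `rank_parameters`).
* **Bifurcation structure** — pseudo-arclength continuation with fold
  detection and Moore–Spence refinement (`continue_equilibria`,
  `bistable_interval`), plus two-parameter fold-curve continuation with
  cusp detection (`continue_fold_curve`).
* **Robust bistability** — steady-state exclusion certificates from a
  McCormick-lifted linear relaxation of `N v(x, p) = 0` over a state box
  times a parameter box, with rigorously checkable Farkas witnesses;
  a box-shrinkage procedure; and the two-box workflow that certifies
  bistability for *all* parameters in a +/-delta% box
  (`exclusion_certificate`, `shrink_robust_box`, `robust_bistability`).

A stiff Rosenbrock ODE integrator with analytic Jacobians is included
(`simulate_network`); the GAL Jacobian has eigenvalues down to about
-7e4 per hour, far outside explicit-method territory.

## Worked example

```r
library(bistacert)

gal <- gal_model()                      # 9 species, 23 reactions, Gex = 1 mM
eqs <- find_equilibria(gal$network, gal$parameters,
                       multistart_spec(n_random = 500,
                                       guesses = gal$reference_states,
                                       seed = 1))
length(eqs)                             # 3 (two stable + saddle)
round(eqs[[1]]$state, 4)
#> 172.8119 172.7962 0.9998 0.9999 0.9999 21.0605 7.5926 0.9999 0.9999

branch <- continue_equilibria(gal$network, gal$parameters, "k5",
                              c(1, 50), x0 = eqs[[1]]$state)
bistable_interval(branch)
#> 12.48413 26.33715
```

The first line of state output is the low-expression steady state in uM
(Gal3p = 172.8, Gal4p:Gal80p = 21.06, ...), matching the published
values to four decimals. The interval is the k5 (basal Gal4p expression)
range over which the switch stays bistable: outside it one of the two
expression regimes disappears through a fold bifurcation.

Robust bistability under simultaneous +/-10% variation of the nine
high-sensitivity parameters:

```r
D <- printed_da_boxes()
r <- robust_bistability(gal$network, gal$parameters, D$D1, D$D2,
                        delta = 10, max_rounds = 40)
r
#> Robust bistability at +/- 10 %: DISJOINT (separated on G3, G3a, G4,
#> G480, G803a, G2, G1)
```

Disjoint certified boxes mean no admissible parameter vector can merge
the two expression regimes: bistability is a robust property of the
model, not an accident of one parameter set. With the packaged
defaults the workflow certifies disjointness up to +/-20% and loses it
at +/-30%, reproducing the published robustness threshold.

## Command line

```sh
Rscript inst/cli/bistacert.R all --model gal --seed 1 --out results/
Rscript inst/cli/bistacert.R bifurcation --param k5 --range 1:50
```

## Limitations worth knowing

The quadratic-Lyapunov certificates are sufficient conditions and
markedly conservative for strongly asymmetric boxes (the level sets are
symmetric ellipsoids). The published domain-of-attraction boxes for the
GAL model are **not** certifiable by these conditions — one corner of
the published high-state box even converges to the *low* state under
direct integration — so this package certifies smaller boxes and backs
every certificate with independent eigenvalue re-checks and simulation.
See `vignettes/bistability-certification.Rmd` for the full discussion.
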