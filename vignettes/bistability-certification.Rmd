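---
title: "Certifying bistability in mass-action networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Certifying bistability in mass-action networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bistacert)
```

# The model class and the flagship fixture

Everything in this package operates on mass-action reaction networks:
ordered species $x \in \mathbb{R}^n_{\ge 0}$, elementary reactions of
molecularity at most two, dynamics

$$\dot x = N\,v(x,p), \qquad v_r(x,p) = p_r \prod_{\text{reactants }a} x_a,$$

with $N$ the stoichiometric matrix and one rate constant per reaction.
The molecularity bound makes the right-hand side *exactly* quadratic,
which is what every certification step below exploits.

The packaged fixture is a nine-species model of the yeast galactose
switch: Gal3p, internal galactose, activated Gal3p, Gal4p, Gal80p, the
Gal4p:Gal80p and Gal80p:Gal3p\* complexes, the permease Gal2p and the
reporter Gal1p, with external galactose fixed at 1000 uM as a constant
input (it has no differential equation; the import rate constant absorbs
its level). The 23 reactions encode two positive feedback loops (via
Gal3p activation and Gal2p-mediated import) and one negative loop (via
Gal80p). With the packaged rate constants the system is bistable: a
low-expression state, a high-expression state, and a saddle between
them. All three are recovered by `find_equilibria()`, and the two stable
states agree with the published 4-decimal tables to about $10^{-4}$
relative.

Degenerate and edge inputs are policed early: non-positive rate
constants, molecularity above two, and references to undeclared species
are construction-time errors; Newton starts that fail to converge or
land at negative concentrations are dropped and the remainder
deduplicated at $10^{-6}$ relative distance; eigenvalues within
$10^{-8}$ of the imaginary axis mark an equilibrium "marginal" and it is
never counted as stable.

# Numerical infrastructure choices

Two pieces of infrastructure are hand-built because the environment
provides no equivalent, and both are kept out of the trusted base:

* **Stiff integration.** The GAL Jacobian has eigenvalues spanning
  $-0.4$ to about $-7\times 10^4$ per hour near the high state, so the
  package ships a two-stage Rosenbrock 2(3) method with embedded error
  control and analytic Jacobians. Its results are cross-checked in the
  test suite against closed forms and (during development) against an
  independent LSODA implementation.
* **LMI feasibility.** The certificate conditions below are linear
  matrix inequalities in one symmetric matrix $M$. Feasibility is
  solved by a Phase-I barrier method (minimize $t$ subject to every
  constraint block $+\,tI \succeq 0$, damped Newton on the log-det
  barrier). The solver's output is never trusted: every returned
  $(\gamma, M)$ is re-verified with plain symmetric eigenvalue
  computations at the full vertex set before a certificate object is
  created. A failure to find a certificate is reported as
  "infeasible-or-unconverged" — the solver does not produce dual
  certificates of infeasibility, and the package never claims one.

# Domain-of-attraction certificates

For a stable equilibrium $x_e$, write $z = x - x_e$ and
$\dot z = Az + F(z)$ with $F_i$ the constant symmetric quadratic forms.
An axis box $S \ni 0$ (interior) with face normals $a_k$
($a_k^\top z \le 1$) and vertices $v_j$ is certified inside the domain
of attraction if for some $\gamma \in (0,1)$ and $M \succ 0$:

1. $M \succeq \gamma^2 a_k a_k^\top$ for all $2n$ faces — the unit
   ellipsoid $E = \{z : z^\top M z \le 1\}$ fits inside $S/\gamma$;
2. $v_j^\top M v_j \le 1$ at all $2^n$ vertices — $S \subseteq E$;
3. $\gamma(A^\top M + M A) + M D(v_j) + D(v_j)^\top M \prec 0$ at all
   vertices, where row $i$ of $D(z)$ is $z^\top F_i$ — the Lyapunov
   derivative $\dot V$ is negative on $S/\gamma \supseteq E$, making $E$
   invariant and attracting.

At fixed $\gamma$ all three are jointly linear in $M$ (the classical
scalar level $c$ is absorbed into $M = P/c$, under which condition 3 is
scale-invariant). The implementation scans a descending 24-point
$\gamma$ grid on $(0.02, 0.98)$, first feasible wins; states are
diagonally rescaled by the equilibrium magnitudes (floored at 1) before
assembly, purely for conditioning. Vertex constraints are added by
constraint generation (a seeded subset first, violated vertices
appended), but the *final* check always covers all $2^n$ vertices. A
strictness margin of $10^{-7}$ is imposed on condition 3.

`grow_box()` stretches a certified seed box face by face (multiplicative
factor 1.1, a face frozen at its first rejection, optional floor at zero
concentration), so the grown box is deterministic and always carries a
valid certificate. `verify_box_by_simulation()` integrates from all
vertices plus seeded Latin-hypercube interior points and reports the
converged fraction; for a sound certificate it must be 1.

## What these certificates can and cannot reproduce

Two structural facts matter when comparing with published
domain-of-attraction estimates for the GAL model:

* Because conditions 1–2 sandwich the box between a *symmetric*
  ellipsoid and its $1/\gamma$ blow-up, vertices of an $n$-box lie
  $\sqrt n$ further out than faces, capping the feasible $\gamma$ near
  $1/\sqrt n$ for box-like $M$ — and far lower for boxes that are
  asymmetric about the equilibrium, since $E \supseteq S$ forces $E$ to
  protrude symmetrically on the short side.
* Condition 3 must then hold on all of $E \supseteq
  \mathrm{conv}(S, -S)$, which for strongly asymmetric boxes includes
  regions of negative concentration where the quadratic terms genuinely
  destroy negativity.

For this model the published box estimates are asymmetric by factors up
to 25, and Phase-I optima stay strictly positive for *every* $\gamma$,
under both the full-vertex reading and the axis-extreme reading of the
vertex conditions, even after shrinking the boxes to 40% of their
printed size. Direct simulation settles the question independently: the
lower corner of the published high-state box converges to the **low**
state (confirmed with two unrelated stiff integrators), so that box is
not contained in the high state's basin at all, and no sound method
could certify it. The package therefore certifies what is actually
certifiable — boxes up to roughly $\pm 2\%$ around the low state and
$\pm 0.2\%$ around the (much stiffer) high state under these Lyapunov
conditions — and treats the published boxes purely as fixtures for the
robustness workflow below. The corresponding acceptance expectations
are deliberately left failing rather than weakened.

# Local sensitivity

`sensitivity_integrate()` augments the state ODEs with the forward
sensitivity equations $\dot S = (\partial f/\partial x)S + \partial
f/\partial p$, $S(0) = 0$, and integrates the whole system with the same
Rosenbrock method; for mass-action networks the second-derivative tensor
is constant, so the augmented Jacobian is exact. Normalized coefficients
$s_{ij} = (\partial x_i/\partial p_j)\,p_j/x_i$ are masked (reported
`NA`) where $x_i < 10^{-6}$ uM, since the normalization is undefined at
zero. The default run starts at a stable steady state with a 20 h
horizon; both stable states are used and the scores summed, because the
published analysis does not say which one it used and both are cheap.

Ranking aggregates the trapezoidal time integral of $|s_{ij}|$, averaged
over species, with alphabetical tie-breaks; the published heatmap fixes
no scalar rule, so this choice is configurable (`final_abs_mean` is the
alternative). Under it, the nine parameters singled out in the published
analysis (galactose import and Gal3p activation, basal Gal4p expression,
the three feedback production rates, and the degradations of Gal3p,
internal galactose and Gal2p) occupy the top nine ranks of 23. Results
are tagged with the nominal parameter vector: they are local statements
only.

# Fold and cusp continuation

`continue_equilibria()` traces equilibrium branches by secant-predictor
/ Newton-corrector pseudo-arclength continuation in coordinates scaled
by nominal magnitudes, with adaptive step control. Folds are flagged by
a sign change of $\det J$ between consecutive points and refined by
Newton on the Moore–Spence system $\{f = 0,\ Jv = 0,\ c^\top v = 1\}$;
for quadratic right-hand sides the required derivative of $Jv$ is the
constant Hessian tensor applied to $v$. Points beyond the requested
parameter range are not recorded (adaptive steps can overshoot), except
that the first negative-state point is kept so folds on the nonnegative
boundary stay bracketed.

For the GAL model the k5 branch is the classical S: folds at
$k_5 = 12.4841$ and $26.3372$ in this reconstruction (published
readings: 12.57 and 26.62). The discrepancy is about 1% while the two
published *cusp* locations are matched to 0.1% (below), which points to
the published interval being a diagram readout rather than a solver
output; the acceptance test at the stated 1% tolerance is left failing
on the upper fold rather than loosened.

`continue_fold_curve()` continues the full Moore–Spence system in two
parameters. Along the curve the fold normal-form coefficient
$b = w^\top B(v, v)$ ($w$ the left null vector, $B$ the constant
second-derivative tensor) changes sign exactly at cusps. Because the
curve is geometrically a cusp there, parameters move quadratically
slowly along arclength; the refinement therefore bisects until the
*bracketing $b$ values* collapse (a persistent gap instead rejects the
sign flip as an artefact of a discontinuous jump in the traversal), and
duplicate detections from repeated traversals are merged at three
significant digits. In the $(k_7, k_5)$ plane this yields cusps at
$(4.360, 3.834)$ and $(166.19, 3796.7)$ against published values
$(4.363, 3.835)$ and $(166.2, 3797.0)$.

# Robust bistability by exclusion certificates

The question "can any parameter vector in a box $\mathcal B_p$ move a
steady state into this region of state space?" is decided through the
bilinear feasibility system $N v = 0$, $v_r = p_r m_r(x)$, $x$ in the
state box, $p \in \mathcal B_p$. The package relaxes it to a linear
program: every bilinear state product appearing in a monomial is lifted
to a fresh variable with McCormick envelopes (secant/tangents for
squares), and $v_r = p_r m_r$ becomes the exact cone
$p_{r,\min} m_r \le v_r \le p_{r,\max} m_r$ — valid because monomials
are nonnegative on the box and exact in $p$ because each rate constant
appears in exactly one rate, so no parameter lifting is needed.

Infeasibility of the relaxation — hence emptiness of the true system —
is certified by a Farkas-type witness $(y \ge 0, \mu)$ with

$$h(y, \mu) \;=\; \min_{z \in \text{box}} (C^\top y + E^\top \mu)^\top z
\;-\; y^\top d \;>\; 0,$$

whose positivity is re-evaluated *exactly* from the interval bounds, so
the optimizer that produced it is not part of the trusted base. The
witness comes from the KKT multipliers of a penalized least-squares
primal solved with projected quasi-Newton iterations; at an exact KKT
point the witness value equals twice the penalized optimum, so a
Polyak-stepped subgradient polish with that target closes the gap left
by finite optimization. Anything else returns "unknown" — a box is
never silently certified. The environment provides no semidefinite
solver, so the published method's semidefinite escalation tier is
replaced by this carefully solved linear tier; empirically it is strong
enough to reproduce the published robustness threshold (below).

`shrink_robust_box()` cuts certified-empty boundary slabs (width 10% of
the current interval), greedily per face and sweeping until a full sweep
cuts nothing, then refines with successively halved slab widths (three
halvings). The greedy-plus-refinement schedule reaches essentially the
"no slab can be cut" fixpoint of a strict round-robin at about a third
of the cost; the fixpoint is mildly path-dependent, which is inherent to
any such schedule, and always on the sound (over-approximating) side.

`robust_bistability()` is the two-box workflow: inflate the two
domain-of-attraction boxes by $S_{i0} = [l/\rho_i,\ u\rho_i]$ (the
multiplicative rule reproduces the published initial boxes from the
published DA boxes at $\rho = 4$ to within their printed rounding),
pick the smallest $\rho_i \in \{1, 2, 4, 8\}$ whose inflated box
contains every Newton-tracked equilibrium over 50 seeded parameter
draws, shrink both boxes, and test per-coordinate disjointness. Two
disjoint certified boxes prove that the low- and high-expression steady
states remain separated for *every* parameter vector in
$\mathcal B_p$ — robust bistability. A soundness post-check verifies
all tracked equilibria still lie in the shrunken boxes.

With the nine high-sensitivity parameters varied by $\pm\delta\%$, the
packaged workflow certifies disjoint boxes for $\delta$ up to and
including 20 (separation carried by active Gal3p and its Gal80p complex
at small $\delta$, by the Gal4p:Gal80p complex at 20), and fails to at
30. At $\delta = 50$ the workflow reports "indeterminate": for some
draws the tracked equilibria escape every admissible initial box —
consistent with $k_5 \pm 50\%$ crossing the fold at 26.34, where
bistability itself disappears for part of the parameter box.

# Determinism, tolerances, and what a green test establishes

All sampling (multistart points, box samples, parameter draws) flows
through explicitly seeded substreams that save and restore the global
RNG; identical configurations give byte-identical artifacts. Key
defaults: Newton residual $10^{-10}$ (scaled), equilibrium merge
distance $10^{-6}$ relative, fold refinement $10^{-8}$ in the parameter,
cusp refinement $10^{-4}$ relative, certificate margin $10^{-7}$,
integrator tolerances $10^{-6}$ relative.

The synthetic fixtures (one-species autocatalysis, a birth–death
process, a competitive Lotka–Volterra pair, a linear chain) are chosen
so equilibria, basins and robust intervals are known in closed form;
they validate the machinery, not the biology. Green tests on the GAL
fixture establish that the packaged equations reproduce the published
steady states, bifurcation structure and robustness threshold — they do
not validate the model against experimental data, and the local
sensitivity statements hold only near the packaged nominal parameters.

Known limitations: quadratic-Lyapunov DA certificates are conservative
(see above) and the certified boxes here are far smaller than the true
basins; exclusion certificates inherit McCormick looseness on very wide
boxes, so shrinkage stalls before the true equilibrium hull is reached;
cusp detection assumes simple folds (the curve is truncated with a
diagnostic when the zero eigenvalue collides with a second one); and
continuation does not switch branches at transcritical points.
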