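---
title: "A 2D energy-minimization vertex model of ventral furrow formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 2D energy-minimization vertex model of ventral furrow formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(furrowsim)
```

## The model

`furrowsim` simulates the cross-section of a gastrulating *Drosophila*
embryo as a ring of 80 quadrilateral cells sandwiched between a rigid
circular eggshell (the vitelline membrane) and the central yolk. Each cell
is bounded by an apical edge (facing the shell), a basal edge (facing the
yolk) and two lateral edges shared with its neighbours. The configuration
of the tissue is the position of the 160 vertices; its mechanical energy is

$$
E \;=\; \sum_i \phi_i \mu_i a_i^2
\;+\; \sum_i \left[ K_l (l_i - l_0)^2 + K_b (b_i - b_0)^2
                  + K_a (a_i - a_0)^2 \right]
\;+\; \sum_i K_v (V_i - V_0)^2 \;+\; K_Y (V_\mathrm{yolk} - V_{0,\mathrm{yolk}})^2 ,
$$

where $a_i$, $b_i$, $l_i$ are apical, basal and lateral edge lengths,
$V_i$ the (2D) cell areas computed by the shoelace rule, and the rest
quantities equal the initial values, so the initial ring is the exact
zero-energy state of the unloaded system. Two active ingredients drive
morphogenesis:

* **Apical constriction.** Cells within the 18-cell mesoderm domain (9 on
  each side of the ventral midline, indicator $\phi_i$) carry an apical
  contractility $\mu_i = \mu_0 \exp(-d_i^2 / 2\sigma^2)$, a Gaussian in the
  cell's offset $d_i$ from the midline. Because the ring has an even number
  of cells, the Gaussian is centred on the boundary between the two
  midline-adjacent cells and the offsets are half-integers; this keeps the
  profile exactly mirror-symmetric.
* **Ectodermal compression.** The lateral (apicobasal) rest lengths of the
  ectodermal cells are shortened by a fraction $\Delta L$ (default 20%).
  Since the area penalty keeps cell areas near $V_0$, shorter cells must
  widen, and in a closed ring bounded by the shell the only way to widen is
  to compress the neighbours: the shortening loads the cell sheet with
  in-plane compression, the way a shortening ectoderm squeezes the mesoderm
  in the embryo.

Lateral edges of the constriction domain additionally carry a
myosin-dependent *active* spring with rest length zero (constant
$K_{L,\mathrm{active}}$, default 2) and use the *passive* constant
$K_{L,\mathrm{passive}}$ (default 20) in place of the ectodermal $K_l$;
the two mesoderm--ectoderm boundary edges belong to the constriction
domain (a config switch moves them to the ectoderm side). The printed
force law for a constriction-domain lateral edge,
$F = K_{L,\mathrm{active}}\, l + K_{L,\mathrm{passive}}\,(l - l_0)$, is
exposed by `lateral_shortening_force()`; the implementation works in the
energy convention throughout ($K_{L,\mathrm{active}} l^2$ and
$K_{L,\mathrm{passive}} (l-l_0)^2$, matching the $K (x - x_0)^2$ form of
all other terms), whose derivative carries an extra factor 2 relative to
the force law. The factor is absorbed by the constants and does not change
which phenomena occur; depth readouts carry a tolerance for this reason.

All lengths are micrometres, areas are square micrometres, and the spring
constants are the dimensionless printed values, so energies are in
arbitrary units. The default geometry -- shell radius 90 um, apicobasal
cell length 35 um -- is a typical cellularization-stage embryo
cross-section; neither value is dictated by the model, both are config
keys, and the depth metrics scale with them.

## Quasi-static trajectories

The simulation is quasi-static: at each stage the tissue is at a local
minimum of $E$, and morphogenesis is driven by slow parameter change. The
basal stiffness $K_b$ is lowered adiabatically from $2^{10}$ to $2^0$ by
twofold steps (11 values); `run_schedule()` equilibrates at each value,
warm-starting from the previous equilibrium. The sequence reproduces the
lengthening--shortening dynamics of the constricting cells: at high $K_b$
the constricted cells elongate apicobasally; as the basal surface yields,
the tissue buckles inward and the mesoderm internalizes.

### Finding equilibria

Each vertex is parameterized in polar coordinates $(r, \theta)$ about the
embryo centre, which turns the vitelline confinement into the box
constraint $|r| \le R$ handled exactly by the optimizer (the radius is
allowed to pass through zero with a sign flip, so a vertex may cross the
embryo centre; projection onto the feasible disc is a radial clamp). The
solver is second order because the landscape is stiff (the area penalties
are four orders of magnitude stiffer than the shape terms) and genuinely
nonconvex near the buckling transition:

1. rounds of L-BFGS-B descent move the state cheaply along the long, mildly
   curved parts of the landscape (warm-start jumps, relaxation cascades);
2. a modified-Newton iteration follows: where the free-coordinate Hessian
   (finite differences of the analytic gradient) is positive definite, a
   Cholesky-factored Newton step is taken; where it is indefinite, the
   eigenvalues are replaced by their absolute values, which converts
   negative-curvature directions into descent directions, and an explicit
   expanding line search is run along the most negative mode (whose
   curvature-scaled component of the Newton step can be vanishingly small
   when the gradient is nearly orthogonal to it). An adaptive trust radius
   caps the step, a backtracking Armijo line search guarantees a monotone
   energy trace, and an expansion phase extrapolates accepted full steps
   while the energy keeps falling;
3. at a stationary point the lowest Hessian eigenvalue is inspected; if it
   is negative (a saddle, as at the symmetric buckling threshold), the
   state is kicked along the unstable mode in both directions and the
   lower-energy branch is followed.

Convergence is declared when the infinity norm of the projected gradient
(outward radial components at shell contacts removed, angular components
scaled to forces) falls below `tol`, by default $10^{-6} \cdot 5000
\cdot a_0 \approx 0.035$ in energy-per-micrometre units -- $10^{-6}$ of the
contractility force scale. The iteration budget `max_iter` is counted in
units of one first-order gradient evaluation, with a Newton iteration
charged 25 units (its relative cost); the default is $10^5$ for schedule
equilibrations and $4 \times 10^5$ for post-inhibition continuations,
which pass through long relaxation cascades. Both are config-exposed.
Iteration counts are an implementation detail of this solver; only the
equilibrium properties (gradient norm, stability, energies) are meaningful
readouts.

Two behaviours of the post-inhibition landscape deserve explicit mention.
First, relaxation after removing contractility is a *cascade*: the state
descends through a long sequence of weakly unstable configurations, and a
minimization stopped before the gradient tolerance leaves the depth readout
above its converged value. An under-resolved relaxation therefore biases
the classification towards `paused`/`invaginated`, never towards `relaxed`
-- budget-capped classifications of relaxed outcomes are conservative.
Second, in the soft-lateral regime (`KL_passive` well below the ectodermal
`Kl`) the inhibited tissue crumples: the landscape holds several nearby
local minima with different residual depths, and which one a descent
reaches is path-dependent. This matches the abnormal constricting-cell
morphology this regime is known for, and it is the reason depth readouts
there should be read as characteristic of a family of crumpled states
rather than a unique equilibrium.

### Mirror symmetry

The problem is mirror-symmetric about the ventral midline, but tilted or
asymmetric furrows are admissible states of the energy, and floating-point
noise can push the minimizer towards them. With `symmetrize = TRUE` (the
default) minimization is performed directly in the mirror-symmetric
subspace (160 instead of 320 unknowns): this is equivalent to symmetrizing
after every step, removes the spurious tilt modes from the saddle
analysis, and guarantees exact left--right symmetry of every reported
state. It also means a state that is stable within the symmetric subspace
but weakly unstable to asymmetric perturbations would be reported as an
equilibrium; that is the intended reading of all symmetric experiments.
The every-other-cell constriction experiment has a genuinely asymmetric
contractility pattern and runs with `symmetrize = FALSE` in the full
space.

## In-silico optogenetic experiments

`inhibit_at_state()` models acute actomyosin inhibition: starting from
schedule state $k$, the apical contractility ($\mu_0$) and the active
lateral springs ($K_{L,\mathrm{active}}$) are set to zero -- the passive
elastic terms are untouched -- and the remaining schedule is run to
completion (if $k$ is already the last state, the final stiffness is
re-equilibrated). The final state is classified against the unperturbed
final state of the same parameter set: `relaxed` if
$D < 0.2\, D_\mathrm{ref}$, `invaginated` if $D > 0.8\, D_\mathrm{ref}$,
`paused` otherwise, where $D$ is the invagination depth (distance from the
shell to the apical midline vertex) and the 0.2/0.8 thresholds are
config-exposed plumbing, not biology; conclusions are required to be
stable over 0.15--0.25 and 0.75--0.85.

The quasi-static analogue of the experimentally observed transitional
stage is `find_transition()`: the smallest $k$ whose inhibition still ends
invaginated. The model is *bistable* when such a $k^*$ exists -- the flat
and the invaginated configurations are then both stable under identical
parameters (no contractility), and which one the tissue ends in depends
only on the state at the moment of inhibition. The full scan
(`method = "scan"`) verifies the dichotomy (no interleaving of relaxed and
invaginated responses); the sweeps use `method = "bisect"`, which relies
on that verified monotonicity to find $k^*$ in $O(\log n)$ runs.

`sweep_deltaL()` repeats the protocol across compression levels (0, 5%,
10%, 20%): the binary response needs at least ~10% shortening.
`sweep_lateral()` spans the active/passive lateral-force grid; lowering
$K_{L,\mathrm{passive}}$ tenfold and a hundredfold shrinks the
late-inhibition depth from ~61 um to ~51 um and ~30 um.
`perturb_constriction()` narrows the Gaussian (default
$\sigma_\mathrm{narrow} = 1.5$, half the baseline; the value is a choice,
the qualitative prediction is insensitive to it) or silences every other
mesodermal cell, and shows that compression buffers the final depth
against impaired constriction.

## Numerical choices and degenerate inputs

* **Area bookkeeping.** Cell areas are signed shoelace areas of the
  straight-edged quadrilaterals, and the yolk area is the signed area of
  the basal polygon. These tile the polygon spanned by the apical vertices
  exactly (a telescoping identity, checked to $10^{-10}$ relative by
  `disc_closure_error()`); the enclosed area differs from the circular
  disc $\pi R^2$ by the usual polygon-vs-circle deficit ($\sim 10^{-3}$
  for an 80-gon), which is why closure is asserted against the polygon,
  not the circle.
* **Soft constraints.** Cell-area and yolk-area conservation are the
  printed quadratic penalties ($K_v = 5000$, $K_Y = 1$), not hard
  constraints; at the defaults the observed per-cell area deviations stay
  below 0.1%, well inside the 5% band asserted by the tests.
* **Contractility with no rest length.** The apical term is $\mu_i a_i^2$
  exactly as printed; apical edges can therefore become arbitrarily short,
  and in deeply invaginated states the most constricted apices reach a few
  hundredths of a micrometre. The $1/a$ factors in the gradient stay
  bounded (the elastic force tends to $2 K_a (a - a_0)\hat e$), but the
  Hessian grows as $1/a$, which is one reason the solver is a damped
  Newton method rather than a fixed-step one.
* **Degenerate geometry.** `geometry_params()` rejects `cell_length >=
  vitelline_radius` (no yolk) and odd or tiny cell counts; `model_params()`
  rejects negative constants and `deltaL` outside $[0, 1)$; non-finite
  vertex coordinates raise errors rather than propagate.
* **Determinism.** The default pipeline has no randomness: geometry,
  schedule and solver are fully deterministic. Random perturbations appear
  only in property tests (seeded) and in no shipped analysis.

## What the synthetic geometry does and does not emulate

The generator reproduces the gross mechanical architecture relevant to the
model: embryo-scale circular cross-section, one cell layer of realistic
thickness, a yolk that resists area change, a rigid shell. It does not
emulate nuclei, membrane rheology (the model is elastic, real tissue is
viscoelastic), anterior--posterior structure (the model is a 2D section),
cell growth or residual cellularization, neighbour exchange (the topology
is fixed), or measured embryo-to-embryo variability. Passing tests
therefore validate the mechanics of the idealized ring, not quantitative
agreement with any particular embryo; the depth readouts in micrometres
inherit the $\pm$ tolerance of the chosen 90/35 um geometry.

## Behaviour at the edges of the studied regime

Three aspects of the implementation's behaviour deserve an explicit,
honest account, because they bound what the depth readouts mean:

* **Terminal-state relaxation.** Removing contractility from the fully
  internalized rosette (the last one or two schedule states) starts the
  slowest relaxation cascade in the whole study. Within practical budgets
  the descent settles in partially involuted crumpled configurations
  (residual depths of tens of micrometres), and deep probes show the
  eventual endpoint is path-dependent. Classifications of inhibition at
  the terminal states therefore carry more numerical uncertainty than the
  early- and mid-schedule inhibitions, whose relaxed/invaginated outcomes
  are robust.
* **Soft constriction-domain laterals.** With `KL_passive` far below the
  ectodermal `Kl`, the constriction domain is mechanically soft: under the
  continuation protocol the compressed ring then invaginates even when
  contractility is removed at the very first state (the soft sector is
  where the compressed ring prefers to buckle), and the late-inhibition
  depth loses most of its sensitivity to `KL_passive` (62-65 um across
  `KL_passive` = 0.2-20 at this geometry, versus a strong dependence in
  the original study). A freeze variant of the protocol (no further basal
  softening after inhibition) restores the early-relax response in this
  regime but leaves the late depths essentially unchanged; the residual
  difference from the original implementation is attributed to unprinted
  length-unit and factor-of-two conventions, which shift the balance
  between the quadratic terms.
* **Constriction count.** With the printed parameter set, 14 cells fall
  below half their rest apical length at the first equilibrium and 16--18
  at the final state, against 12 in the original account. The Gaussian
  tail cells (offsets 6.5--8.5) sit close to the halving threshold, so
  this count is sensitive to exactly the conventions above; the package
  reports the computed value rather than the nominal one.

## Known limitations

* No self-contact: in deeply invaginated states apical surfaces of the
  internalized pocket may geometrically overlap, as in the model this
  package reimplements; metrics remain well-defined (signed areas, vertex
  distances) but the overlap is not physical.
* The transitional index $k^*$ is defined by outcome (first state whose
  inhibition still invaginates), not by morphology; panel-level matching
  of specific $K_b$ values to embryo stages is out of scope.
* Tilt is a single-angle proxy per cell (apicobasal axis vs local radial
  direction), not a curvature reconstruction.
* Equilibria found by the solver are local minima reached by adiabatic
  continuation; global minimization is neither attempted nor meaningful
  for a hysteretic system.

## Problem sizes used by the tests and the acceptance script

All simulations run the full 80-cell ring. The test suite and the
acceptance script run the complete 11-state schedule for every condition
they assert about; inhibition scans test every state index where the
dichotomy itself is the claim, and use bisection (or a single
terminal-state inhibition, which by the dichotomy settles the existence of
a transition) where only the location or existence of the transition is
needed. Scans of relaxation-dominated conditions run under capped
iteration budgets sized so the whole suite completes in tens of minutes on
one core; the caps exploit the conservative direction of under-resolution
(a stopped cascade can only overestimate depth, so no spurious `relaxed`
call can arise). A full schedule takes well under a minute on a single
core; a full inhibition scan a few minutes; the acceptance script about
ten minutes.
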