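---
title: "Methods: gait structure of a bipedal SLIP with passive swing legs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait structure of a bipedal SLIP with passive swing legs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

The biped is a point mass on two massless linear-spring legs. A leg in
stance pushes from its stationary foot anchor toward the center of mass
with force `k (lo - l)`; a leg in swing is a massless pendulum with an
infinitesimal foot mass, driven by a passive torsional spring of
oscillation frequency `omega` toward its neutral leg swing angle (NLSA)
`phi_i`. Because foot mass and torsional stiffness are infinitesimal, the
swing legs exert no force on the body and their own elastic energy is
negligible: the model is conservative, and the touchdown reset of a
massless leg does no work. Everything is normalized by body mass, rest leg
length and gravity (`m = lo = g = 1`); speeds are in `sqrt(g*lo)`, times
in `sqrt(lo/g)`, stiffness in `m*g/lo`.

Angles are measured from the downward vertical through the hip,
counterclockwise positive, with travel along `+x`; a foot planted ahead of
the body has a positive leg angle (`xc = x + y tan(alpha)`). The swing
equation's signs are fixed by three physical requirements: the torsional
term restores the leg toward `phi`; in ballistic flight the gravity and
body terms cancel exactly, leaving harmonic oscillation about `phi` at
exactly `omega` (tested to 0.1%); and for a stationary body the leg is a
stable hanging pendulum with frequency `sqrt(omega^2 + g/lo)` (the
implementation's sign-convention witness, asserted in the tests).

## Two evaluation modes: event detection vs. prescribed event times

The package integrates the hybrid dynamics in two deliberately different
ways.

`simulate_stride()` is event-driven: adaptive Dormand–Prince (relative
tolerance `1e-9`, absolute `1e-11`) with touchdown (`y = lo cos(alpha)`
crossed downward), liftoff (the same function crossed upward, the spring
back at rest length), and flight apex (`ydot = 0` falling) located by an
Illinois root solve on exact re-integration, to event residuals around
`1e-12`. Simultaneous events within `1e-9` are processed
touchdowns-first. This is the right tool for simulating from arbitrary
states and for defining the apex-to-apex return map.

The gait search, however, uses the boundary-value form
(`gait_system_residual()`): the four contact times and the stride time are
unknowns alongside the reduced apex state, segments between events are
integrated with *prescribed* contact modes, and the four leg-length
contact conditions plus state periodicity close the system (12 constraints
against 13 unknowns once the anchor is counted; the horizontal position is
cyclic and bookkept as stride length). Two properties make this the only
workable formulation here:

* the residual is smooth in every unknown, including across event-time
  collisions, so the walk–run and skip–asymmetric-run timing degeneracies
  are *regular* roots rather than breakdown points; and
* nothing constrains the swing foot's height *between* events. Much of
  the published gait structure — the whole symmetric running branch, whose
  apex height is below the rest leg length, and the high-speed hopping and
  skipping solutions — has the swing foot transiently below ground
  mid-flight. An event-detecting integrator truncates those strides at the
  scuff and cannot represent the solutions at all; the prescribed-times
  form reproduces them. The package records for every solution whether an
  event-detecting stride also reproduces it (`stride_consistent()`).

A solution is *admissible* when the solver converged (residual below
`1e-8`; the integrator noise floor makes a few `1e-9` the practical
limit), no touchdown is premature, and the swing amplitude is finite.
**Premature touchdown** is implemented as the spec prescribes: contact
while the leg still rotates in the direction of travel,
`sign(xdot) * alphadot > 0.05` at the solved touchdown. The threshold is a
small finite rate rather than zero because branches are born at
bifurcations with infinitesimally anterior contacts that immediately give
way to retraction. This criterion reproduces every nominal headline number
but is also the least certain modeling choice in the package: the original
study applies its version of the rule unevenly across branches, and the
package's coupled existence boundaries (where hopping/skipping/running
cease as the NLSA grows or shrinks) come out systematically narrower than
the published ranges. An alternative reading (contact *earlier than* the
solved touchdown during anterior swing) was implemented and rejected
because it would terminate the nominal high-speed branches that the
published analysis continues to speed 29.

## Finding gaits and tracing branches

The model is conservative, so periodic solutions form one-dimensional
energy families. A damped Gauss–Newton least-squares solver (SVD
pseudo-inverse steps, trust-region cap, step halving) closes the free
direction with an anchor — total energy, apex speed, apex height, or
stride time — or projects minimal-norm onto the manifold (`anchor =
"none"`, used by parameter tracking; a pseudo-arclength polish removes the
residual floor left by the numerically near-null family direction).

Bootstrapping is constructive rather than by blind search:

* the zero-speed vertical hop is exact (body bounces on both springs, legs
  hanging); the forward-hopping branch bifurcates from this family where a
  transverse multiplier crosses +1. Crossings come in pairs indexed by the
  number of half swing oscillations per flight; the fundamental pair
  (about half an oscillation, apex height ~1.03–1.05) contains the
  published hopping branch, whose eigenvector has no leg-angle component —
  legs vertical at apex, retracting before contact.
* symmetric running satisfies the half-stride symmetry (advance half a
  stride = swap the legs), which reduces the search to one stance phase,
  two contact times and seven swap-periodicity conditions
  (`seed_symmetric_running()`, structured multistart under a fixed seed).
* skipping and asymmetric running are reached from hopping through the
  leg-desynchronizing bifurcation (below) or by uncoupling the neutral
  angles, which breaks the pitchfork and deforms hopping smoothly into
  skipping.

Branches are continued by pseudo-arclength predictor–corrector in the full
candidate space (state + event times), with secant tangents, adaptive step
length (halve on corrector failure, grow 1.4 on easy convergence), and
termination on degenerate solutions (premature touchdown, fall), the speed
cap, fold-back onto the start (closed loops), or the point budget. The
swing-amplitude 1.7-rad limit is recorded per solution and available as a
cap but is *not* applied by default: the published analysis uses it only
to restrict the displayed coupled-sweep range, and capping at 1.7 rad
would cut the nominal branches at apex speed ~15.7, far below the
published maximum ~29.

## Floquet multipliers and transitions

The monodromy matrix is a central finite-difference Jacobian of the apex
return map (step `1e-6`) in the six reduced coordinates, evaluated in the
prescribed-times form (contact times slaved to the perturbed state by a
Newton solve) so it stays defined on scuffing solutions. One multiplier
equals +1 (the family direction); the touchdown reset erases the incoming
leg velocity, so zero multipliers occur structurally and the return map is
not invertible.

At leg-synchronized (hopping) solutions with equal neutral angles, the
monodromy commutes with the leg-swap involution and block-diagonalizes;
the 2×2 antisymmetric (desynchronizing) block is probed with two
perturbations, and `det(M_a - I)` is the hop–skip test function — its sign
changes are bracketed and bisected in arclength until the critical
multiplier is within `1e-3` of +1. Branch switching displaces the fixed
point along the critical eigenvector (both signs, growing amplitude) with
the displacement held fixed during the re-solve.

Walk–run and skip–asymmetric-run transitions are not multiplier crossings
but event-time collisions (one leg's touchdown meets the other's liftoff).
Because event times are unknowns, each is solved directly as a bordered
system (periodicity + zero gap), seeded from a bracketing sign change
along the branch; `transition_curve()` continues the same bordered system
with a neutral angle freed as an extra unknown, tracing the transition's
locus through parameter space through folds.

## Parameter sweeps

Solutions are carried through parameter space by warm-started re-solves
with adaptive step halving (`track_gait()`), anchored at fixed apex speeds
when drifting onto neighboring families (notably zero-speed swinging
families) must be prevented. Existence boundaries
(`phi_branch_boundary()`) carry several speed-anchored representatives,
re-trace the branch and reseed from its quartiles when all of them fail,
and bisect the final interval. This is an operational definition of
"the family exists here"; it can only undercount, and the ledgered
acceptance results show it does undercount relative to the published
ranges.

## The synthetic-kinematics generator

Real inputs to the fitting module would be markerless pose tracks (eye and
tail-base midpoint as the center of mass, lines to the feet as leg angles)
from 500-fps video. `generate_fixture()` emulates them: one model stride
sampled at 500 fps converted to dimensionless time with a representative
jerboa scale (effective leg length 0.06 m, so one frame = 0.0256 time
units), independent Gaussian noise per position channel (default sigma =
0.005 lo), and velocities as central finite differences of the *noisy*
positions — the same scheme the cost applies to the model, so
differentiation noise enters both sides consistently. What the generator
does not emulate: pose-estimation outliers and autocorrelated tracking
error, stride-to-stride variability (real animals are never exactly
periodic), and out-of-plane motion. A green fitting test therefore
establishes parameter identifiability under idealized periodic data, not
tracking robustness.

## Fitting

`fit_slip()` minimizes the integrated squared deviation of positions and
velocities (all four channels weighted equally, trapezoidal quadrature on
the empirical grid) over free parameters (default `omega`, `phi_l`,
`phi_r`; `k` is held at 20 unless freed, matching how the published
analysis fixed stiffness). The empirical stride duration anchors the model
stride time; each candidate parameter vector re-solves the periodic gait
warm-started from the previous solution, so the search walks the joint
space of parameters and solutions. The optimizer is Nelder–Mead
(derivative-free; no sequential quadratic programming implementation is
available in the dependency set, and the cost's inner solve makes finite
difference gradients noisy). Horizontal position is aligned by shifting
both stride recordings to start at `x = 0`.

## Numerical choices

* integration: `rtol 1e-9`, `atol 1e-11`; event residuals < `1e-10`;
  energy drift along a stride < `1e-6 E` and stance-constraint drift
  < `1e-8` (asserted by tests).
* Gauss–Newton tolerance `4e-9` on the residual norm (the `1e-8` contract
  with headroom above the integrator noise floor); trust region 0.5;
  SVD truncation `1e-10` relative, except `3e-7` in the minimal-norm
  projection phase where the family direction must be projected out.
* classification tolerance `1e-3 T` (equalities before strict orderings;
  gaits labeled from the merged stance intervals and the aerial phases
  they leave: none = walking, one = skipping/hopping, two =
  symmetric/asymmetric running by aerial-phase equality).
* degenerate inputs: stance with `|alpha| >= pi/2` or `y <= 0` is a
  geometric failure; more than 8 contact events per stride is treated as
  chattering; candidates with reordered per-leg event times are rejected
  with a penalty.

## Known limitations

* Walking is classified and representable as event patterns, but the
  Poincaré section is a *flight* apex, so walking solutions (which have no
  aerial phase) are not found as fixed points; the walk–run point is
  located from the running side as the aerial phase vanishes. This matches
  the section choice of the source analysis.
* The published per-trial fitted states (the skipping trial tables) are
  not exactly reproducible — per-trial leg stiffness is not printed — and
  one tracked branch segment at strongly uncoupled angles does not reach
  the printed trial speed; the package's jerboa-parameter gait is a
  synthetic stand-in at the same parameters.
* Existence boundaries in the neutral-angle sweeps depend on the
  premature-touchdown criterion and on branch-following heuristics; they
  are systematically narrower than the published ranges (see the
  admissibility discussion above).
* Left-advanced and right-advanced gaits are related by the leg-swap
  symmetry at equal neutral angles; the package canonicalizes to the
  right-leg-first ordering and does not analyze transitions between the
  two chiralities.
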