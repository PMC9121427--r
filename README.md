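# slipgait

Gait structure and gait transitions of a bipedal spring-loaded inverted
pendulum (SLIP) with passive torsional-spring swing legs — the template
model family used to explain how small non-cursorial bipedal hoppers
(jerboas) switch between hopping, skipping, running and asymmetrical
running across their whole speed range.

## The model

A point mass `m` moves in the sagittal plane on two massless linear-spring
legs (rest length `lo`, stiffness `k`). Leg angles `alpha_l`, `alpha_r` are
measured from the downward vertical (counterclockwise positive, travel
along +x). In flight each leg is driven by a passive torsional spring
toward its neutral leg swing angle (NLSA) `phi_l` / `phi_r` with
oscillation frequency `omega`:

    xdd = Fx/m,   ydd = Fy/m - g
    swing:   add_i = -(1/lo) [ xdd cos(a_i) + (g + ydd) sin(a_i) ] - omega^2 (a_i - phi_i)
    stance:  xc_i - x - y tan(a_i) = 0   (holonomic foot constraint,
             differentiated twice for the stance leg acceleration)
    touchdown (y = lo cos a_i):  ad_i reset so the foot velocity is zero

All quantities are normalized by `m`, `lo` and `g`; the standard
configuration is `k = 20 m g/lo`, `omega = 6.5 sqrt(g/lo)`. The model is
conservative, so periodic gaits form one-dimensional branches as total
energy varies; gaits are fixed points of the flight-apex Poincaré return
map, found as roots of the full constraint system (periodicity plus the
four touchdown/liftoff contact conditions, with the event times as
unknowns) and continued by pseudo-arclength. Transitions appear as
+1-Floquet-multiplier bifurcations (hop–skip) and event-time collisions
(walk–run, skip–asymmetric-run).

## What the package provides

* `simulate_stride()`, `poincare_map()` — event-driven hybrid integration
  (adaptive Dormand–Prince with root-refined touchdown/liftoff/apex
  events, implemented in C++).
* `find_gait()` / `find_gait_bvp()`, `classify_gait()`, `gait_metrics()` —
  periodic-gait search and labeling (walking, hopping, skipping, symmetric
  and asymmetric running).
* `continue_branch()`, `monodromy()`, `detect_bifurcation()`,
  `branch_switch()`, `locate_timing_degeneracy()`,
  `nominal_gait_structure()` — branch continuation and the transition
  machinery.
* `track_gait()`, `phi_branch_boundary()`, `track_transition()`,
  `transition_curve()`, `sweep_coupled()`, `sweep_uncoupled()` —
  neutral-leg-swing-angle parameter sweeps.
* `fit_slip()` (with `coef`/`predict`/`plot`/`residuals` methods),
  `trajectory_cost()`, `r_squared()` — least-squares fitting of model
  gaits to kinematic stride recordings.
* `generate_fixture()`, `write_trajectory()`, `write_branch()`,
  `load_config()` — synthetic 500-fps-style kinematics and plain-text IO.

## Worked example

Find the zero-speed vertical hop, a forward hop, and classify it:

```r
library(slipgait)
p <- slip_params()          # k = 20, omega = 6.5, phi_l = phi_r = 0

hop0 <- seed_forward_hop(p)         # branches off the vertical-hop family
hop <- find_gait_bvp(hop0, p, anchor = "speed", value = 2)
hop
#> slip_gait: hopping
#>   apex: y0 0.990002, xdot0 2 | E 2.99 | residual 2.65e-10
#>   times: l td/lo 0.3384/0.7061, r td/lo 0.3384/0.7061, T 1.04448
#>   duty 0.352, stride length 2.075, avg speed 1.986
```

The apex height `y0` is in leg lengths, speeds in `sqrt(g*lo)`, times in
`sqrt(lo/g)`; both legs touch down and lift off together (hopping), with a
duty factor of 0.35 at apex speed 2.

The full nominal analysis — hopping branch, hop–skip bifurcations, the
skipping/asymmetric-running continuum and its transitions, the symmetric
running branch and the walk–run point:

```r
ns <- nominal_gait_structure(p)
ns$walk_run$s[2]                                  # walk <-> run speed
#> 1.196921
sort(sapply(ns$skip_ar_transitions, function(s) s$s[2]))
#> 7.685446 28.101166                              # skip <-> asym-run speeds
ns$max_speed
#> 29.23821                                        # fastest solution found
```

## Acceptance script

`scripts/acceptance.R` recomputes the analysis end to end at the standard
parameters — the nominal gait structure with its transition speeds, the
coupled neutral-angle existence boundaries of hopping/skipping/running,
and the uncoupled transition-speed catalogue — and writes the resulting
numbers as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The run takes on the order of ten minutes on one CPU.
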