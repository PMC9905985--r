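---
title: "Modelling age-related passive muscle stiffening in planar reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling age-related passive muscle stiffening in planar reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(reacharm)
```

## The model

`reacharm` simulates goal-directed reaching of a planar upper limb in the
horizontal plane (no gravity torques): a stationary upper chest with the
shoulder at the origin, and three moving segments — upper arm, forearm, hand —
connected by range-limited hinge joints. Each joint is actuated by one
antagonistic pair of Hill-type muscles, six in all. Each muscle produces

f_tot(l, l', t) = f_max [ f_a(l, l') a(t) + f_p(l) ],

where `f_max` is the maximum isometric force, `f_a` the active
force–length–velocity scaling (normalized so `f_a(l0, 0) = 1` at the optimal
length `l0`), `a(t)` the activation state, and `f_p` the passive elastic force
of the intramuscular connective tissue (IMCT),

f_p(lbar) = s_p (exp(r_p (lbar − l_p)) − 1)  for lbar > l_p, else 0,

with `lbar = l / l0`. The three passive parameters are the levers through
which ageing is emulated: the scale `s_p` (amount of IMCT), the rate `r_p`
(its material stiffness) and the slack length `l_p` (the normalized length at
which it engages). Nine parameter triples define the study conditions: a
no-passive-force reference (`l_p = 1.3`, beyond any attainable length) and
eight ageing scenarios A–H crossing low/high values of each parameter
(`s_p` ∈ {0.05, 0.075}, `r_p` ∈ {5, 8}, `l_p` ∈ {1.1, 1.0}). Scenario labels
are ordered by severity, measured as the work needed to elongate a muscle
from slack to the model's maximal attainable normalized length
(`elongation_work()`); the ordering A < B < … < H is asserted in the test
suite at the computed length range.

Muscle excitation is converted to activation by a chain of three first-order
lags (time constants 15 ms each), giving the third-order excitation-to-
activation dynamics: activation is a smoothed, delayed image of excitation,
confined to [0, 1].

## Parameter choices

The arm and muscle constants are the package's own defaults, chosen as
round, anthropometrically reasonable values for a right arm and then locked:
segment lengths 0.30/0.25/0.18 m, masses 2.0/1.2/0.5 kg, centre-of-mass
offsets at 45–50 % of segment length, inertias of slender rods, chest bar
0.44 m toward the contralateral side. Joint ranges are shoulder −10°…150°,
elbow 0°…150°, wrist −45°…45°, with the reset posture at mid-range
(70°, 75°, 0°).

Muscle paths are linear in joint angle (constant moment arms), which fixes
two properties by construction that the passive-force design requires:

* every muscle sits exactly at `lbar = 1` in the reset posture, so with
  `l_p = 1.0` any movement away from it stretches one muscle of a pair past
  its slack length;
* the moment-arm-to-`l0` ratio is set per joint so the maximal normalized
  length over the whole feasible joint box is 1.25, safely below 1.26, the
  threshold above which no muscle would ever produce passive force. The
  acceptance script re-derives this maximum from a dense 200³ joint sweep.

Maximum isometric forces (800/600/200 N per pair, shoulder/elbow/wrist) give
torque capacities around 21/15/4 N·m — far above what the reaches demand, so
failures are never strength-limited; they emerge from control and passive
forces, which is the phenomenon under study. The active force–length curve is
a Gaussian of width 0.45 in `lbar`; the force–velocity curve is a Hill
hyperbola (curvature 0.25, `v_max` = 10 l0/s) with a saturating eccentric
branch (plateau 1.5) whose slope matches at zero velocity.

## Planning and control

Each reach tracks a straight endpoint path with the minimum-jerk profile
`s(τ) = 10τ³ − 15τ⁴ + 6τ⁵`; duration follows an average-speed rule
`T = max(0.4 s, d / 0.5 m s⁻¹)`, and a 1 s homing window follows the planned
arrival. The endpoint reference is converted to joint-space references by
closed-loop damped-least-squares inverse kinematics integrated on the control
grid, with a weak null-space attraction toward mid-range angles resolving the
third degree of freedom. The IK damping (0.005 m) and null-space rate
(0.5 s⁻¹) were set so the held reference converges onto the target to within
a few micrometres — two orders of magnitude below the strictest accuracy
threshold reported (0.01 mm), so the reference itself never limits the
measured errors. Straight paths to some distal-right targets necessarily
cross a region outside the reachable workspace (the feasible band there is
narrower than the reach); the planner deliberately does not clamp such paths,
and the tracking error this induces is part of the measured behaviour.

The differential IK can jam at a joint-box corner for targets reachable only
on a different IK branch (elbow-wrapped postures in the lower workspace
lobe). When the IK reference misses the target terminally by more than 1 mm,
the planner falls back to solving the closest reachable posture directly
(multi-start box-constrained minimization of the endpoint error) and rides a
joint-space minimum-jerk reference to it over the movement duration. The
endpoint reference — and therefore the movement-error metric — keeps the
straight path, so the large deviation such reaches require remains visible in
`e_mv`; for targets outside the workspace the fallback reference simply
saturates at the closest reachable point.

The controller runs at 1 kHz with zero-order-hold excitations. At each step
it (i) forward-simulates its internal, noise-free copy of the full model over
the prediction time `t_pred` holding current excitations, (ii) forms desired
torques as inverse-dynamics feedforward along the reference plus a PD
correction on the predicted joint-space error, and (iii) inverts desired
torques to excitations. The seven control parameters are the per-joint PD
gains and `t_pred` (an integer number of control steps).

The torque-to-excitation inversion enforces the no-co-excitation rule: per
joint, the agonist is the muscle whose pull matches the sign of the desired
torque; only it receives excitation, computed from its moment arm and `f_a`
at the (predicted) operating point, with a first-order lead compensation
(capped at a factor of 2) for the activation lag over `t_pred`, clamped to
[0, 1]. The inversion deliberately models only the *active* muscle
apparatus. Passive muscle forces are an unmodeled disturbance that the PD
gains must overcome — that asymmetry is the causal pathway of the whole
study: it is why stiffer passive scenarios develop static stopping-short
errors at elongated postures, why re-tuning pushes gains up with scenario
severity, and why those higher gains in turn court oscillatory instability.
Had the inversion compensated passive torques exactly (the controller knows
the model, so it could), every ageing scenario would perform identically and
there would be nothing to study. Three further design points matter here:

* the decaying activation of the unexcited antagonist is *not* fed back into
  the demand. Compensating it term-by-term makes the discrete loop ratchet:
  each side's demand includes cancelling the other's activation, the paired
  demands alternate with per-step gain above one, and both activations climb
  until the joint saturates. Leaving that correction to the PD feedback keeps
  the loop stable; the residual overlap of decaying antagonist and rising
  agonist activation is exactly the emergent co-activation the co-activation
  metric quantifies.
* with zero tracking error and a resting reference the inversion returns
  exactly zero excitation, so the reset posture is a true equilibrium.
* the desired-torque signal is smoothed by a two-tap average before
  inversion: holding excitations constant inside the forward prediction
  makes the discrete loop's period-2 (Nyquist) mode marginally unstable,
  and the two-tap average annihilates exactly that mode at a cost of half a
  control step of delay.

## Numerics

The coupled system has 24 states (3 joint angles, 3 velocities, 18 activation
states). It is integrated with fixed-step RK4 at 4 substeps per control
interval (0.25 ms), with the control grid as mandatory step boundaries. A
self-convergence test verifies that halving the substep changes the homing-in
error by well under 1 %. The controller's internal prediction integrates the
same equations with RK4 at steps of at most 5 ms, which the slowest relevant
dynamics (15 ms activation lags) resolve comfortably. Joint limits are
enforced by a stiff one-sided penalty torque (500 N·m/rad) with damping
(5 N·m·s/rad) engaged only beyond the limit, keeping the vector field smooth
for the integrator. Diverging trajectories (oscillatory blow-ups can be
violent) are frozen at the last finite state and flagged unstable; their
metrics then report the correspondingly large errors instead of NaNs.
Activation states are projected back onto [0, 1] after each step to remove
round-off excursions.

The simulator draws no random numbers anywhere: reaches are bit-for-bit
reproducible, and randomness is confined to the genetic algorithm, which is
seeded.

## Workspace and target sets

The geometrical workspace is estimated by sweeping the joint box on a dense
grid, rasterizing endpoint images at 1 cm resolution, dilating by one cell
(so every sample is strictly enclosed) and extracting the enclosing contour.
Boundary accuracy is therefore about the raster resolution; points on the
polygon count as inside. Three target sets mirror the study design: a
four-target tuning sequence near the workspace edges (distal left/forward/
right plus a proximal-right point placed just inside the proximal boundary
along a 30° ray); a rectangular 5 cm grid over the workspace bounding box
(out-of-workspace points kept for mapping, excluded from statistics); and
concentric boundary arcs covering the distal boundary and a 20 cm band inside
it, split into the right side (arcs about the shoulder, traced by the straight
arm over the shoulder range) and the left side (arcs about the fully flexed
shoulder's elbow point, traced by the straight forearm+hand over the elbow
range). Inner arcs on the right partly fall outside the workspace because the
right-hand reachable band is narrower than 20 cm; they are flagged and
excluded from aggregates like any other out-of-workspace target.

## Metrics and failure taxonomy

The homing-in error `e_h` is the time-averaged endpoint-to-target distance
from the planned arrival time to the end of the simulation; the movement
error `e_mv` is the time-averaged deviation from the reference during the
movement. Both use trapezoidal integration (step-size robust) and are
reported in millimetres, matching the reporting thresholds 0.01/0.1/1/10 mm.
Co-activation per joint is the time-average of `min(a_flexor, a_extensor)`
over the whole simulation — the standard reading of simultaneous non-zero
activation; it is emergent, since co-excitation is forbidden.

Failures are classified from the homing-phase distance signal: `success` when
`e_h ≤ 1 mm` (the coarser reporting threshold); otherwise `oscillatory` when
the distance direction reverses more than 6 times with peak-to-peak amplitude
above 1 mm (or the integrator blew up), else `stopping_short`. The reversal
count and amplitude floor are configurable; the defaults were chosen once on
the two canonical failure shapes (smooth settling at a distance vs sustained
oscillation through the target) and are not tuned per scenario.

## Controller tuning

The seven control parameters are optimized per scenario by a mixed-integer
genetic algorithm minimizing mean `e_h` over the four-target sequence: six
real genes (gains, bounds 0–300 N·m/rad and 0–50 N·m·s/rad, from the
closed-loop bandwidth that the activation lag can support at the arm's
inertias) and one integer gene (`t_pred` in ms, 0–60, bracketing the ~45 ms
total activation lag). Tournament selection (size 3), uniform crossover,
Gaussian mutation (σ = 10 % of range), integer random-walk mutation, and two
elites; elitism makes the best objective non-increasing, which the tests
assert. Re-tuning for scenarios B–H injects the baseline (scenario A) and
reference optima into the initial population, so it can never end worse than
baseline on the tuning targets.

The package ships the parameter sets produced by its own tuning runs
(`inst/extdata/control_params.csv`, provenance in the adjacent JSON):
"reference" (tuned with no passive force), "baseline" (tuned for scenario A)
and "retuned" (tuned per scenario). Desk-scale runs (population 30–20,
generations 50–30, four targets) complete in tens of minutes on one core;
the problem sizes used throughout the tests (sub-sampled boundary sets,
reduced GA sizes) are stated where they are used.

## What the synthetic conditions do and do not show

All inputs are generated by the package itself: there is no measurement
noise, no sensing delay, and the controller's internal model is exact. The
simulations therefore isolate one causal pathway — passive stiffening versus
control — under idealized conditions; they are a lower bound on the errors a
real (noisy, imperfectly calibrated) system would show. The model omits
tendons and series elasticity, short-range stiffness and other
history-dependent muscle effects, 3-D shoulder anatomy, and any adaptation of
movement speed or planning; conclusions about those mechanisms are outside
its reach. Passive parameters are identical across all six muscles, so
muscle-specific stiffening patterns are not represented.

## Known limitations

* The discrete excitation loop has a small noise floor: near marginally
  stable gain settings, round-off-seeded limit cycles of order 0.1 mm can
  appear. The tuned parameter sets sit inside the stable region, where the
  floor is far below the strictest reporting threshold.
* The workspace boundary is a raster estimate; targets within about one
  resolution cell of the true boundary can be mis-flagged either way.
* With constant moment arms, muscle lengths are linear in joint angle;
  moment-arm variation with posture (and the force–length operating-point
  drift it causes) is not modelled.
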