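---
title: "Estimating ground contact forces from kinematics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ground contact forces from kinematics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmest)
```

## The problem

Controlling a lower-limb exoskeleton (or running any inverse-dynamics
analysis of gait) requires the contact forces and moments (CFMs) under the
feet. Measuring them needs force plates or instrumented insoles; estimating
them from kinematics alone runs into a structural obstacle in double
support: the rigid-body balance provides six equations, while the two feet
carry twelve unknown contact components (six forces, six moments). Even
after the sole moments are neglected, the six remaining force components
cannot be solved — forces exchanged along the line joining the two contact
points are invisible to the resultant, so the 6×6 coefficient matrix of the
balance system has rank 5 *in every posture*, axis-aligned or not
(`force_balance_matrix()`, `placement_balance_matrix()`,
`rank_invariance()`). The double-support body is statically indeterminate.

`cfmest` implements a two-stage resolution of that indeterminacy:

1. **Geometric reduction (the DDCS).** Each foot's contact system is
   collapsed to a single force at its centre of pressure (COP), dropping the
   sole-plane moments and the sole-normal free moment. D'Alembert's
   principle turns the dynamic problem into statics: the whole-body
   gravity-plus-inertia loads are aggregated into one wrench about a body
   point `O0` and reduced to the central (screw) axis — a force line plus a
   collinear couple. Force balance requires the two COPs and that axis to be
   coplanar, so fixing the left COP position `a` (measured heel→toe)
   determines the right COP position `b = f(a)` in closed form
   (`coupled_b()`). A per-sample *dynamic decoupled coordinate system* is
   then erected at the intersection `O` of the COP line and the central
   axis, with X along the COP line (`ddcs_frame()`). In this frame the
   balance system becomes block-solvable: five force components follow
   directly (`solve_decoupled()`), leaving exactly two free scalars — `a`
   and the axial split fraction `k` with `FLX = k FX`,
   `FRX = (1 − k) FX` (`split_axial()`). Twelve unknowns become two.

2. **Minimum-energy resolution.** Among all balance-consistent contact
   distributions, the estimator selects the one minimising a
   stiffness-weighted sum of squared joint moments,
   `E = Σ f_i T_i²`. The rationale is an elastic-joint model: if joint i has
   effective stiffness `K_i`, its elastic potential is `T_i²/(2 K_i)`, so
   `f_i ∝ 1/K_i`. Joints are grouped into four classes — hip
   flexion/extension (reference weight 1), hip ab/adduction (`q0`), knee
   (`q1`), ankle (`q2`) — with shipped defaults
   `[q0, q1, q2] = [1.0, 2.1, 0.1]`, interpretable as ankles being much
   stiffer than knees. Only ratios matter: scaling all factors by a positive
   constant rescales `E` but moves no minimiser (tested property; this is
   also why calibration can hold `q0` fixed).

In single support no optimisation is needed at all: the central axis'
ground pierce point *is* the COP, and the contact force is exactly the
negative aggregate inertial force (`single_support_solution()`). Phase
classification itself uses that pierce point against each foot's 6-point
sole contour (`classify_support()`).

## The optimisation

Joint moments come from a recursive Newton–Euler backward pass over the
segment tree (`joint_moments()`): the moment at a DOF is the negative
axis-projection of all D'Alembert and contact loads on its distal subtree.
Because the pass is linear in applied loads, `T` is affine in the contact
forces, and for fixed `a` the contacts are affine in `k` — so `E(k)` is an
exact quadratic `e0 k² + e1 k + e2` with `e0 ≥ 0`, minimised in closed form
at `k* = −e1/(2 e0)`. The estimator evaluates the affine moment map at
`k = 0` and `k = 1` and assembles `e0, e1, e2` from per-joint-class sums;
this is numerically identical to fitting the quadratic through three `E`
probes (a tested invariant) but lets any factor combination be evaluated
from one precomputation, which is what makes the calibration grid cheap.

The outer parameter `a` is handled by plain grid traversal over its
feasible interval — the sub-range of `[0, lf]` where the coupled `b(a)`
also lands on the other foot (`feasible_a_range()`). Traversal rather than
descent is deliberate: `E(a)` need not be unimodal (the closed-form `k*`
re-optimises at every `a`), and a grid cannot be trapped in a local
minimum. Defaults and numerical choices:

* `grid_step = lf/200` (≈1.3 mm for a 0.266 m foot) — below any
  physiologically meaningful COP resolution.
* Ties in `E` within 1e-9 relative break toward smaller `a`, then smaller
  `|k − ½|`, making output deterministic.
* Grid points with `e0 ≤ 1e-12` (energy flat in `k`, e.g. a vanishing
  axial force) are skipped with a diagnostic; a sample where every point is
  skipped is reported as a per-sample estimation failure, never a crash.
* `k` is unconstrained by default, as the closed-form minimiser assumes;
  `clamp_k = TRUE` projects it into `[0, 1]` for friction-plausible output.
* The X-moment about `O` (along the COP–COP axis) has no solvable
  counterpart among the retained components and is dropped after the frame
  transform; its magnitude is logged per sample (`dropped_MXD`) as a
  model-error diagnostic. On the synthetic gait it is of order 1e-3 N·m
  against ~1e2 N·m load moments.
* Degenerate geometry (COP line parallel to the constraint plane,
  P on the X axis, coincident COPs) raises named errors; the per-sample
  driver records them and continues.

Conventions fixed where the underlying geometry leaves freedom: the world
frame is right-handed Z-up with gravity `(0, 0, −9.81)` m/s² and ground
plane z = 0; `a` and `b` are measured from the heel toward the toe; the
point-in-contour rule is boundary-inclusive (even–odd with a 1 mm edge
band), because misclassification at phase transitions is the method's
dominant failure mode; a pierce point inside neither contour is treated as
double support with a warning flag rather than an error, so trajectories
remain processable. Multi-DOF hips are ordered flexion/extension then
ab/adduction. `O0` rides rigidly on the pelvis and all wrench algebra is
done in world coordinates — the frame choice affects no result, only
bookkeeping.

## Calibration

`calibrate_factors()` fits `(q1, q2)` by flat traversal of the feasible
region (0, 5] at step 0.1 (2500 combinations, mirroring the protocol the
default factors come from), minimising the mean squared error of the six
estimated force components against a reference table, over double-support
samples only — single support is closed-form and carries no factor
information. Each grid point reproduces exactly what `estimate_cfm()` would
return for those factors (shared precomputation and tie-breaks), so a
reference generated by the estimator with planted factors is recovered with
zero objective at the planted grid point.

## What the synthetic data emulates — and what it does not

Because the estimator is validated without external data, the package
generates its own scenes:

* `generate_model()` builds a 12-segment body (pelvis, torso with head,
  2 × {upper arm, forearm, thigh, shank, foot}; arms welded; 8 actuated
  DOFs) from standard segment-mass and length fractions of height and
  mass. Feet are heel–toe segments with rectangular-hexagon 6-point sole
  contours (half-width 0.029·height).
* `generate_gait()` produces strictly periodic joint trajectories with
  *analytic* first and second derivatives, so rigid-body consistency holds
  to machine precision. The pelvis sways laterally with a flattened
  (tanh-shaped) wave; the flattening parameter and amplitude are designed,
  via a quasi-static ZMP model (`com_y − (z̄/g)·com_ÿ`), so the pierce
  point dwells inside each contour for the requested single-support
  fraction. Hips counter-roll to keep the feet on their tracks, pelvis
  height tracks the tilted-leg drop so each sole reaches the ground at
  mid-stance, swing knees flex to clear the ground, and ankles keep the
  soles level. Defaults — stride period 6 s, double-support fraction 0.20,
  step length 0.12 m — describe a slow, deliberate walk chosen so the
  inertial excursions stay well inside the synthetic support polygons.
* `generate_truth()` synthesises reference CFMs that satisfy the decoupled
  balance exactly: either smooth seeded `(a, k)` profiles ("arbitrary"), or
  `(a, k)` planted at the brute-force energy minimum for stated factors
  ("energy_minimal"), the basis of the recovery experiments.

These kinematics are deliberately *exercise-grade, not biofidelic*: the
cadence is slow, foot–ground contact is reached only at mid-stance (no
impact, no heel-strike transient, no sliding), there is no measurement
noise, soft tissue, or marker artefact, and the truth wrenches inherit the
method's own contact idealisation (pure forces at on-axis COPs). Passing
tests therefore demonstrate internal correctness of the geometry, the
decoupling, the optimiser and the calibration — not accuracy against
force-plate recordings of real walking, which would require external data
and a contact model the method itself does not use.

The independent cross-checks use different machinery than the paths they
verify: a 10⁴-point particle cloud with finite-difference accelerations for
the wrench aggregation; Poinsot equipollence at random probe points for the
screw reduction; 1-D root bisection for the COP coupling; dense line
sampling for the frame origin; an independently coded even–odd
point-in-polygon comparison; hand-computed two-link statics for the inverse
dynamics; and a brute-force `(a, k)` search (grid in `a`, derivative-free
Brent in `k`, no quadratic assumption) for the optimiser
(`exhaustive_minimum()`). Problem sizes in the shipped tests — e.g. 100
double-support frames for the balance and oracle-equivalence checks, five
seeds for the recovery experiment, six samples under the full 2500-point
calibration grid — were chosen as the smallest scenes that exercise every
code path with comfortable statistical margins.

## Known limitations

* The sole moments (two in-plane components and the normal free moment) are
  neglected by construction; turning or pivoting gait, where the free
  moment matters, is outside the model.
* Feet are line segments: the COP is confined to the heel–toe axis, so
  deliberate medio-lateral weight shifting within a planted foot is
  invisible to the estimator.
* The energy hypothesis presumes natural, unforced movement; co-contraction
  or voluntary load redistribution without postural change cannot be
  recovered from kinematics alone.
* Flight phases (running) have no contact solution; the classifier assumes
  at least one foot loaded.
* Support classification is per-sample and stateless; no temporal
  hysteresis is applied, so isolated misclassifications near phase
  transitions pass through unsmoothed.
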