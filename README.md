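# cfmest — sensor-free ground contact force and moment estimation

`cfmest` estimates the ground contact forces and moments (CFMs) under each
foot of an articulated human (or human–exoskeleton) model **from joint
kinematics alone** — no force plates, no instrumented insoles. It is aimed
at exoskeleton control and gait-analysis work where per-foot reactions are
needed but plantar sensing is impractical.

## The method

In double support the rigid-body balance is statically indeterminate: six
equations face twelve unknown contact components, and even with the sole
moments neglected the 6×6 coefficient matrix

```
A = [ I3   I3  ]
    [[pL]× [pR]×]
```

has rank 5 in *every* posture — forces exchanged along the line joining the
two contact points cancel in the resultant. `cfmest` resolves this in two
stages:

1. **Dynamic decoupled coordinate system (DDCS).** The whole-body
   D'Alembert wrench is aggregated about a body point `O0` and reduced to
   its central (screw) axis: a force `F` along a line, plus a collinear
   couple. Coplanarity of the two centres of pressure (COPs) with that axis
   couples the COP positions — fixing the left COP parameter `a` yields the
   right one in closed form,

   `b = −[(PM × F) · PC] · |CD| / [(PM × F) · CD]`,

   and a per-sample frame is erected at the intersection of the COP line
   with the central axis, X axis through both COPs. There the balance
   decouples: five force components solve directly, leaving exactly two
   scalars — `a` and the axial split fraction `k` (`FLX = k·FX`).

2. **Minimum-energy hypothesis.** The remaining `(a, k)` minimise a
   stiffness-weighted sum of squared joint moments, `E = Σᵢ fᵢ Tᵢ²`, with
   per-class weights `[q0, q1, q2] = [1.0, 2.1, 0.1]` (hip ab/adduction,
   knee, ankle; hip flexion/extension = 1). Joint moments come from a
   recursive Newton–Euler pass, are affine in the contacts, so `E(k)` is an
   exact quadratic minimised in closed form at `k* = −e1/(2e0)` while `a`
   is scanned by grid traversal over its feasible interval.

Single support needs no optimisation: the central axis' ground pierce point
is the COP, and the reaction is exactly `−F`. Support phase itself is
classified from that pierce point against each foot's 6-point sole contour.

## Worked example

Everything below is synthetic and seeded — the package generates its own
anthropometric model, a kinematically consistent slow walk, and estimates
the reactions:

```r
library(cfmest)

model  <- load_body_model(generate_model(height = 1.75, mass = 70))
motion <- generate_gait(model, gait_params(n_cycles = 2, dt = 0.1))
fit    <- estimate_cfm(model, motion)
summary(fit)
#> CFM estimate over 121 samples ( 101 single, 20 double, 0 failed )
#>   peak vertical force  L/R: 689.45 / 689.45 N
#>   mean double-support energy E: 1254.2
#>   mean |dropped X-moment|: 0.003887 N m
#>   split fraction k range: -0.6435 ..  1.6444
```

The peak vertical reaction (~689 N) is the 70 kg body's weight (686.7 N)
plus a small inertial surcharge, carried entirely by the stance foot in
single support. The dropped X-moment — the one balance component the DDCS
cannot resolve, logged as a diagnostic — is ~4 mN·m here, five orders below
the load moments. Per-sample output:

```r
head(subset(as.data.frame(fit), phase == "double"))
#>  time  phase      a      b       k         E      flz      frz
#>   1.3 double 0.1928 0.1678 -0.6435 2314.6975 528.8344 154.6576
#>   1.4 double 0.1982 0.1507  1.2840  951.8280 440.3279 241.0613
#>   1.5 double 0.2008 0.1337  0.4796  339.7535 340.2242 340.3176
```

During this double-support transfer the left (trailing) foot's COP — `a`,
metres from the heel — pushes off around the ball of the foot while the
right (leading) foot's COP `b` moves back toward its freshly landed heel,
and the vertical load migrates from `flz` to `frz`. `plot(fit)` draws the force traces;
`calibrate_factors(model, motion, reference)` refits `[q1, q2]` on a
(0, 5] × 0.1 grid against reference forces, and
`generate_truth(..., mode = "energy_minimal")` plants ground truth for
recovery experiments. A thin command-line front end with `estimate`,
`synth`, `calibrate` and `rank-check` subcommands lives in
`inst/cli/cfm.R`.

## Scope

Sole moments (including the normal free moment) are neglected by
construction; feet are heel–toe line segments, so the COP cannot leave
that axis; flight phases are out of scope. The bundled gait generator is
exercise-grade, not biofidelic — see the methods vignette
(`vignettes/cfm-estimation.Rmd`) for the model, the numerical choices, and
what the synthetic validation does and does not demonstrate.
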