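---
title: "A reduced-order knee model for ACL strain during jump landing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order knee model for ACL strain during jump landing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneestrain)
```

This vignette is the package's own account of its science: the mechanical
model and its assumptions, the parameters that matter and why they hold
their default values, what the synthetic cohort does and does not emulate,
the numerical choices, and the known limitations.  It states no empirical
result that the test suite and the analysis scripts do not themselves
compute.

## 1. The mechanical model

### Rigid bodies and coordinates

Bone is three orders of magnitude stiffer than knee soft tissue, so the
femur, tibia and patella are rigid.  Coordinates are right-handed with X
anterior, Y proximal, Z lateral for a right knee; units are mm, N and
N·mm internally, degrees at every user interface.  The femur is fixed to
ground (as in cadaver-style rig tests that constrain the femur), the tibia
is the solved 6-DOF body, and the patella is a massless marker that
co-rotates with the tibia about the flexion axis.  That slaving choice makes
the extensor linkage passive-neutral under pure flexion — the patellar
ligament spring engages only through tibial translation — which is the
1-DOF analogue of the patella gliding in the trochlear groove.

### Ligament bundles

All cruciate/collateral structures are straight, tension-only line elements
between a femoral and a tibial insertion (no wrapping): two ACL bundles
(anteromedial AM, posterolateral PL), two PCL bundles, three fibres each for
the MCL and LCL.  Each carries the standard piecewise force law with a
quadratic toe region below `2*eps_l` and a linear region above, `eps_l =
0.03` by default — the conventional transition strain for one-dimensional
ligament elements; it is exposed per bundle in
`inst/extdata/bundle_parameters.csv`.

Slack lengths come from full-extension pre-strains: `L0 = Lr / (1 + eps_r)`
with `Lr` the inter-insertion distance at the reference pose, so
`bundle_strain()` at full extension reproduces the assigned pre-strain to
machine precision (this is asserted at 1e-12 in the tests).  The ACL
pre-strains are 6 % (AM) and 10 % (PL).  The AM = 6 / PL = 10 pairing is an
inference from the bundles' flexion behaviour — the near-isometric bundle is
the AM — not an explicitly documented assignment; swapping the two values in
the parameter file explores the alternative.

### Secondary structures and contact

The patellar ligament (k = 545 N/mm), medial and lateral patellofemoral
ligaments (16 and 12 N/mm) and two meniscal-horn stand-ins (180 N/mm) are
linear, tension-only springs.  The femoral anchors of the patellofemoral and
horn springs sit on the transepicondylar (flexion) axis, which renders them
isometric under pure flexion — the reduced-order counterpart of their
near-epicondylar anatomy — so they act purely as translational restraints.
The menisci themselves are not modelled; the horn springs are a synthetic
stand-in for the translational resistance the meniscus-horn complex
provides, and are labelled as such.

Articular contact is a frictionless penalty between two femoral condyle
spheres (radius 30 mm, centres on the flexion axis) and a flat tibial
plateau plane: normal force = 2000 N/mm × penetration, no tangential
component.  Contact energy, forces and moments are mutually consistent
(the wrench is the exact gradient of the penalty energy), which the energy
ledger relies on.

### The default geometry is synthetic

The digitised cadaver insertion sites behind the original model are not
published.  The default knee places insertions from published anatomical
ranges (ACL ~30 mm running anterior-distal on the tibia to the posterior
femoral notch; collaterals spanning epicondyles to the proximal tibia and
fibular head) and then fixes the femoral offsets relative to the flexion
axis so that the passive bundle kinematics show the canonical pattern every
arthroscopy text reports: a near-isometric AM bundle, a PL bundle that
slackens steeply with flexion, a PCL that engages gradually.  This placement
was done once, at design time; the resulting coordinates are frozen in
`default_knee_geometry()` and in the model JSON schema, and everything
downstream treats them as data.  The default knee is explicitly generic —
it is not any specimen.

## 2. Solvers

`solve_static()` runs a damped Newton iteration on the generalized residual
(force and moment about the tibia origin, optionally expressed on the tibia's
own axes so that, e.g., "anterior" stays plateau-anterior at 90° flexion).
The stiffness matrix comes from central differences of the analytic residual;
a backtracking line search on the residual norm, Levenberg-style damping, and
an eigen-direction escape for saddle stalls make it robust on the protocol
sweeps.  Convergence means every free residual component below 1e-6 N
(or N·mm).  Solutions start from the reference pose (or the previous sweep
point, for continuation) and are deterministic.

`simulate_dynamic()` integrates the free tibial DOFs with semi-implicit
Euler under elastic, contact, applied and viscous forces, with the knee
flexion angle prescribed from the boundary series.  Defaults: 4 kg
translational mass, dt = 2e-4 s (the contact frequency with that mass is
~700 rad/s, so the step sits well inside the stability bound), damping
2 N/(mm/s).  An energy ledger accumulates trapezoidal work of the applied
loads and of the constraint actuators that drive the prescribed tibia and
patella motion, books the integrator's numerical damping as dissipation, and
must balance work-in against kinetic + elastic + dissipated energy; the test
suite gates landings at 2 % imbalance and halving dt changes reported peaks
by under 1 %.

Joint angles use a floating-axis decomposition (flexion about the femoral
medio-lateral axis, ab/adduction about the floating anterior axis, axial
rotation about the tibial long axis), with the documented sign convention
for a right knee and a warning at the gimbal configuration near 90°
abduction.

## 3. Muscle actions and the ankle moment

With the femur grounded, muscle actions reduce to equivalent tibial forces:

* **Quadriceps** pull along the patellar tendon at the tibial tubercle.  The
  tendon-to-tibial-shaft angle is the well-documented sagittal relation
  `20° − 0.25·flexion` — anterior shear near extension, nil around 80°.
  This single relation is what makes the quadriceps the main ACL antagonist
  in the model.
* **Hamstrings** pull posterior-proximally toward the ischium in the femur
  frame (a posterior drawer plus compression; protective).
* **Gastrocnemius** contributes a small anterior lean plus compression at
  low flexion (antagonist), fixed at 15°.
* **The sagittal ankle moment** maps to a posterior force on the proximal
  tibia of `soleus_share × moment / shank_length` (defaults 0.55 and
  400 mm): the uniarticular soleus rotates the proximal tibia posteriorly,
  while the biarticular gastrocnemius share of the plantar-flexion moment is
  already applied as muscle force and must not be double-counted.  How an
  ankle moment reaches an isolated knee is genuinely open; this lever-arm
  mapping is the package's documented choice, and both parameters are
  exposed.

## 4. The synthetic landing cohort

`cohort_spec()` / `generate_profile()` emulate the *shape* of jump-landing
boundary conditions: single-peaked muscle-force bursts shortly after
touch-down, smooth hip/ankle angle excursions, hip/ankle moment bursts, a
ground-reaction-force (GRF) burst used only as a timing/normalisation
descriptor.  Curves are piecewise cubic Hermite segments with zero slope at
the control points (C1, no overshoot); control parameters are drawn from
envelope means ± sd.

Default envelope magnitudes are literature-plausible for a recreational
adult cohort — quadriceps ~2.75 kN, hamstrings ~0.4 kN, gastrocnemius
~1 kN, GRF ~2.6 body weights, ankle moment ~130 N·m, hip 20→50°, ankle
−15→+20° — and were calibrated once, together with the soleus share, so
that the simulated cohort reproduces the landing-strain scale reported for
in-vitro jump-landing work (cohort means of a few percent relative strain,
ankle moment reducing the mean by roughly a third).  They are defaults of a
stand-in, not digitized study data, and every one is overridable.

Two structural choices deserve emphasis:

* **Knee flexion = hip + ankle dorsiflexion.**  The isolated knee needs a
  flexion trajectory; the sagittal-chain sum of the generated hip and ankle
  angles is the simplest mapping that couples landing "softness" to knee
  excursion, and `max_knee_flexion` is computed from it, never drawn.
  All summary descriptors (angles at peak GRF, peak velocity) are computed
  from the stored curves, so they are self-consistent to 1e-9.
* **Latin-hypercube stratification.**  Each envelope parameter's n strata
  are assigned to the n participants by a seed-dependent permutation
  (deviates rescaled to unit within-cohort variance, truncated at ±2.5 sd).
  A 10-participant cohort is meant to stand in for one fixed study
  population, so each generated cohort should be representative of the
  envelopes rather than a noisy i.i.d. draw; stratification keeps cohort
  means on the envelope means across seeds while preserving the ±2 sd
  participant spread.

What the generator does **not** emulate: measured inter-muscle correlation
structure (only trunk is coupled to hip), bilateral asymmetry, GRF-driven
joint loading (GRF is a descriptor, not an applied force), and any
frontal/transverse-plane content.  Passing tests therefore demonstrate the
mechanics and pipeline on plausible sagittal inputs, not agreement with any
individual's measured landing.

## 5. Landing outputs and statistics

Relative ACL strain uses the touch-down gauge: `(L(t) − L_td)/L_td`, with
the touch-down state taken as the quasi-static equilibrium under the initial
loads (so no artificial transient contaminates the gauge).  Both bundles are
reported; the headline "peak ACL strain" is the larger bundle peak, a
convention the result object makes explicit.  The landing phase is the
profile window, 250 ms from touch-down by default.

The statistical pipeline follows the conventional order for a positive
response: z-normalisation for screening, bivariate Pearson r with
t-distribution p-values (per-test alpha 0.05, no multiplicity correction),
Box–Cox by profile likelihood on a λ grid over [−2, 2] (step 0.01, λ = 0 is
the natural log), then OLS on the transformed response.  The "contribution"
column uses sequential (type-I) sums of squares in the order the predictors
are entered, so contributions plus error total 100 % by construction.  The
reference evaluator `predict_peak_strain()` uses the published coefficients
on the ln(percent-strain) scale — the constant 9.09 with angle magnitudes of
tens of degrees is only dimensionally consistent if strain is in percent —
and warns outside a [−30, 120]° angle envelope.  A positive knee-flexion
coefficient alongside negative hip/trunk/ankle coefficients means the
equation must be used jointly, at realistic posture combinations, not one
angle at a time.  When the pipeline is fitted to this package's own
10-profile cohorts, the fitted coefficients are sample-specific (n = 10);
the analysis script reports them alongside the reference equation rather
than in place of it.

## 6. Numerical choices and degenerate inputs

* Solver tolerance 1e-6 N; finite-difference steps 1e-6 mm / 1e-7 rad;
  saddle escapes capped at 8 before a solver error that carries the last
  residual.
* Sweeps use 21 points by default and carry the previous equilibrium as the
  next guess (continuation); the flexion sweep's 0° entry is the passive
  reference configuration itself, where bundle strains equal their
  pre-strains.
* Zero-length bundles at initialization, non-uniform time grids, freeing
  the prescribed flexion DOF, missing JSON keys (error carries a
  JSON-pointer path), non-rotation orientations, constant predictors
  (flagged, not dropped), rank-deficient designs (error names the collinear
  column) and single-profile cohort arms (sd undefined) all fail fast with
  specific messages.
* Model JSON is written with 17 significant digits, so save → load is the
  identity on every numeric field.
* Problem sizes in the shipped tests and scripts: 21-point protocol sweeps,
  10 + 10 landing runs at dt = 2e-4 s over 250 ms, 100-replicate regression
  recovery at n = 200 — sizes chosen so the whole analysis reruns in a few
  minutes on a laptop core.

## 7. Known limitations

Rigid bones and sphere-on-plane contact ignore cartilage compliance and
meniscal load sharing; bundle lines of action ignore wrapping, so deep-flexion
cruciate geometry is approximate; muscle lines of action are effective
sagittal relations, not moment-arm curves from imaging; the ankle-moment
mapping is a lever-arm reduction of a joint-spanning mechanism; the cohort
is synthetic and sagittal-only.  Within those bounds the model reproduces
the qualitative validation surface (bundle flexion behaviour, laxity-test
monotonicity, valgus response) and the landing-phase strain scale, which is
what a desk-scale screening tool for extrinsic, trainable landing factors
needs.
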