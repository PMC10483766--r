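---
title: "Predictive simulation of walking with ankle-foot orthoses: model and methods"
author: "afosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive simulation of walking with ankle-foot orthoses: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afosim)
```

# The scientific problem

People with bilateral plantarflexor weakness walk with excessive ankle
dorsiflexion, persistent knee flexion and reduced push-off, which raises the
metabolic cost of walking.  A dorsal-leaf-spring ankle-foot orthosis (AFO)
can substitute for the weak calf muscles: during stance it stores elastic
energy as the shank rotates over the foot and returns it at push-off.  Its
bending stiffness (Nm per degree of ankle rotation) is the key prescription
parameter — too flexible and the excessive dorsiflexion persists, too stiff
and push-off work is blocked — and the energy-optimal stiffness differs
between patients.

`afosim` implements a planar predictive-simulation pipeline for studying
what drives that optimum: a forward-dynamic neuromusculoskeletal walking
model with a reflex-based controller, model variants with graded
plantarflexor weakness, altered passive muscle stiffness, added body mass
and enforced walking speed, AFO stiffness sweeps, and an analysis layer that
extracts from each sweep the stiffness minimizing the energy cost of
transport and the minimum stiffness normalizing individual gait parameters.

# The walking model

## Skeleton

Seven rigid segments (trunk-pelvis, left and right thigh, shank and foot)
linked by nine degrees of freedom: pelvis translation (x, y), pelvis
rotation, and hip, knee and ankle flexion per leg.  Conventions: knee angle
0 = full extension with flexion positive; ankle 0 = neutral with
dorsiflexion positive; all user-facing angles in degrees, internal state in
radians.  The equations of motion are assembled at every step from the
segment-tree kinematics (analytic Jacobians; mass matrix
`M = sum(m_i J_i' J_i + I_i g_i' g_i)`) and solved directly — equivalent to,
but much cheaper than, general multibody machinery at this problem size.
Inertial parameters are a planar reduction in the style of the OpenSim
Gait2392 model, scaled to a 75.17 kg adult; they live in the packaged YAML
configuration (`default_model_path()`), never in code, and are documented
defaults rather than claims about a specific subject.

Knee ligaments are a rotational spring (2 Nm/degree) with damper
(0.2 Nm/degree/s) engaging beyond 120 degrees of flexion or when the knee
extends beyond 10 degrees of flexion; the damper acts only while the spring
is engaged, so the passive knee is strictly torque-free inside the
(10, 120) degree window.  The AFO is a massless bilateral torsional spring
at the ankles with neutral angle 0 degrees; stiffness 0 reproduces the
no-AFO model bit-exactly.  AFO mass and footplate stiffness are outside the
model's scope.

## Integrator

Fixed-step semi-implicit (symplectic) Euler at `dt = 1e-4 s` by default.
At this step the passive drop test drifts in total mechanical energy by
about 3e-4 per simulated second — acceptable for shooting-based gait
optimization, where contact dissipation dominates.  For the energy audits
the package provides an error-controlled reference integrator
(`simulate_passive(..., method = "reference")`, LSODA at 1e-10 tolerance),
whose drift on the same test is below 1e-4/s; the audits in the test suite
use it, as the fixed-step scheme's first-order energy error would otherwise
be what is measured.

## Muscles

Nine Hill-type musculotendon units per leg (tibialis anterior, soleus,
gastrocnemius, vastus, rectus femoris, hamstrings, biceps femoris short
head, gluteus maximus, iliopsoas), each representing its functional group.
The equilibrium formulation is used: normalized fiber length is a state;
each step the tendon force (exponential-toe curve, strain 0.049 at the
isometric force) is balanced against the fiber force
`a f_L(l) f_V(v) + f_P(l) + beta v` (Gaussian active force-length, width
0.45; exponential passive curve engaging above optimal length; hyperbolic
force-velocity with eccentric plateau 1.4 and fiber damping beta = 0.1),
and the fiber velocity is solved from the monotone balance by bisection.
Pennation follows the constant-thickness model.  Activation dynamics are
first order with 10 ms activation and 40 ms deactivation constants, updated
exactly per step.  Maximal contraction velocity is 10 optimal lengths/s.
Muscle paths are planar origin/via/insertion polylines in segment frames;
moment arms follow from differentiation of path length and were checked
against physiologic values at neutral posture (e.g. soleus ankle arm
-5.3 cm, tibialis anterior +4.0 cm, vastus knee arm 4.5 cm).

## Plantarflexor weakness and passive stiffness

`apply_weakness(model, s, p)` reduces the soleus and gastrocnemius maximal
isometric force to `(1 - s) F_max` while rescaling their normalized passive
fiber and tendon curves by `1/(1 - s)`, so the *absolute* passive curves
match the unimpaired model exactly (verified to 1e-9 relative in the test
suite).  The passive plantarflexor force is then multiplied by `p`
independently of weakness.  `p` acts on the passive fiber curve — the
muscle's passive stiffness — while the tendon stays matched to the
unimpaired model.

## Contact

Two Hunt-Crossley spheres per foot (heel and toe, radius 3.2 cm):
`F_n = k d^1.5 (1 + c d_dot)` floored at zero (never adhesive), with
velocity-regularized Coulomb friction (`mu = 0.9`, regularization
0.05 m/s).  The constants are configuration values chosen so that quiet
standing settles with millimetre-scale penetration; the standing audit
recovers total vertical ground reaction force equal to body weight within
0.5%.

## Reflex controller

A gait-phase state machine per leg (early stance, late stance, liftoff,
swing, landing) advances on foot load and on the sagittal ankle-to-pelvis
distance, with separate load-on/load-off thresholds providing hysteresis.
Within each phase, muscle excitations are sums of constants, positive force
feedback (`K_F` times delayed normalized tendon force) and length feedback
(`K_L max(0, l - l_0)` on delayed normalized fiber length), clipped to
[0, 1]; the hip muscles additionally receive a proportional-derivative
trunk-lean term in stance (extensors excited, hip flexor inhibited when
leaning forward of the target).  Neural delays are 20 ms for the distal
(ankle) muscles and 10 ms proximally.  The wiring table — which source
feeds which target in which phases — lives in the configuration, follows
the classic positive-force-feedback reflex-walking lineage (soleus,
gastrocnemius and vastus F+ in stance; tibialis anterior L+ with soleus F-
inhibition; swing-phase hip flexion via iliopsoas L+ and C; hamstring and
short-head biceps L+ to decelerate the swinging leg), and is optimized, not
hand-fixed: the flattened vector of all gains, offsets, phase thresholds
and the initial pose (41 parameters) is the CMA-ES search space.  Both legs
share one parameter set (bilateral weakness, symmetric gait assumed).

## Energetics

A standard activation/maintenance + shortening-heat + mechanical-work rate
model: per muscle
`rate = m (A a + M a f_L(l)) + S F max(0, -v) + max(0, -F v)`, clamped at
zero, with muscle mass from `F_max l_opt rho / sigma`
(sigma = 0.25 MPa, rho = 1059.7 kg/m^3), `A = 40`, `M = 74` W/kg muscle and
`S = 0.25`; plus a basal rate of 1.2 W/kg body mass.  Gross cost of
transport is the windowed metabolic energy divided by body mass and
distance (J/kg/m).  No specific published coefficient set is claimed;
absolute COT therefore carries model-choice uncertainty and trends across
conditions are the meaningful surface.

# The optimization protocol

The composite objective is
`0.15 * COT + 0.1 * head acceleration + 1e8 * falling + 0.1 * joint-range
violation + 1e4 * plantarflexor activation above 50%`.  Design choices
where the functional forms were open: head acceleration is the
time-averaged magnitude of the trunk-top point acceleration over the
analysis window; a fall is pelvis height below 80% of its initial value or
integrator divergence (the bout then terminates); the joint-range penalty
integrates knee hyperextension beyond 0 degrees and ankle excursion beyond
±60 degrees; the activation penalty integrates the soleus/gastrocnemius
excess above 0.5 over time (smooth in bout length, unlike an instantaneous
maximum).  Bouts last 10 s with a 0.3 m/s minimum speed, entered as a
quadratic shortfall penalty; enforced-speed conditions add a quadratic
deviation from the target speed, since the study design states speeds were
set without giving a mechanism.  Energy, head-acceleration and penalty
terms are accumulated over the window after a 2 s transient.

CMA-ES (standard weighted-recombination formulation with rank-one/rank-mu
covariance updates, implemented in `cmaes_minimize()`) searches the
box-normalized parameter space.  The study protocol runs six seeds per
condition and terminates each when the mean improvement over the trailing
500 generations falls below 0.001%, with a hard cap of 2000 generations;
the best seed is the outcome, and a condition where every seed falls is
flagged infeasible rather than fatal.  Inside the search only, falling
candidates are ranked by survival time (the fall penalty is reduced by up
to 60% in proportion to the fraction of the bout completed); the reported
cost always carries the full binary penalty.  Without this shaping the
1e8 penalty is flat across all falling candidates and CMA-ES receives no
gradient until the first complete walk is found.

The packaged configuration ships with controller initial values obtained by
running a staged, reduced-budget version of this optimization on the
unimpaired model (locomotion-shaped stages of increasing bout length).
They encode a forward-stepping gait — phase transitions cycle, the legs
swing and load alternately, and the model progresses at roughly
0.25 m/s — that sustains itself for about half of a 10 s bout at the
2e-4 s search step before balance is lost.  They are a starting point, not
a converged solution: discovering a self-stable 10 s limit-cycle gait in
this 41-dimensional reflex space empirically needs the full multi-seed,
plateau-terminated protocol (tens of thousands of bout evaluations), which
is cluster-scale by design.  Desk-scale runs — the regime all examples and
tests use (single seeds, a handful of generations, coarse stiffness
grids) — exercise the full machinery end to end but should not be expected
to produce converged walking; the energy-response analyses on synthetic
sweep tables are the desk-scale surface with known ground truth.

# The in-silico experiment

`build_variant()` composes, in order, plantarflexor weakness
(40/60/80/90%), passive stiffness scaling (20-200% of normal), segment-mass
scaling (+10%, +30%, muscle forces unchanged) and an optional enforced
speed (0.75/1.0/1.2 m/s); the 80% weakness model at free speed is the
baseline.  `run_sweep()` optimizes the controller at each stiffness of the
grid — 0 (no AFO) plus ten levels in exact 0.87 Nm/degree increments to
8.7, extended to 12.18 when no interior optimum appears.  The printed
range endpoints 0.9 and 8.7 with a 0.87 increment are mutually
inconsistent; the grid uses exact multiples of 0.87, reading 0.9 as a
rounded display.  Per-condition results are cached on disk keyed by a hash
of the compiled model, stiffness, seeds and protocol, so sweeps resume
without recomputation and a completed sweep re-runs with zero new
simulations, bit-exactly.

## Extracting the optima

`fit_optimum()` fits a third-order polynomial to COT versus stiffness by
least squares — cubic because the response need not be symmetric about its
minimum — and takes the argmin of the fit over the sampled domain, computed
from the stationary points in closed form (numerically stable quadratic
root form, so exactly quadratic data does not divide by a vanishing cubic
coefficient) and cross-checked against a dense grid search in the tests.  A
minimum on the domain boundary raises a flag to extend the grid.  Fit
quality is the Pearson correlation between fitted and observed values;
`r > 0.7` counts as reliable, below that the result is marked unreliable
but still reported.  The energy-cost reduction is the fitted COT at zero
stiffness minus the fitted COT at the optimum (both from the fit, for
consistency under noise).

`normalization_stiffness()` fits the same cubic per gait parameter and
root-finds (bracketed bisection, 1e-8 tolerance on K) the smallest
stiffness at which the fit crosses the normative threshold in the
normalizing direction: maximal stance dorsiflexion down to 17.2 degrees,
minimal stance knee angle down to 4.2 degrees, peak ankle moment up to
1.17 Nm/kg (normative mean minus 2 SD, since the ankle moment levels off
below the normative mean), and minimal external knee moment up to
0.34 Nm/kg.  The knee-moment direction deserves a note: with extension
positive, the weak models' stance minimum is a flexion (negative) moment,
and normalization means rising to the normative bound of 0.34 — the fit
crosses upward.  A parameter already on the normal side at zero stiffness
needs no orthosis (`K_norm = 0`); a fit that never reaches its threshold is
flagged rather than extrapolated.  `compare_optima()` treats each simulated
model as an individual subject and compares energy-optimal against
normalizing stiffnesses with an independent two-sample pooled-variance
t-test — mirroring the study design even though the data are naturally
paired; the per-model paired differences (mean ± SD) are reported
alongside.

# Validation metrics

Gait cycles are segmented at upward crossings of the vertical ground
reaction force through 20 N, time-normalized to 101 points by linear
interpolation, and summarised per variable.  Agreement with a reference
band (mean ± SD over 101 points) is quantified by the zero-lag Pearson
cross-correlation with the band mean — no lag search, as cycle
normalization already phase-aligns the curves — and by the RMSE in SD
units: the root-mean-square of the *pointwise* SD-normalized deviation.
Pointwise normalization is the reading under which a curve lying exactly at
mean + 2 SD everywhere scores exactly 2.0, the conventional 95%-band
boundary.

`spm_ttest()` performs the 1D statistical parametric mapping two-sample
t-test over the gait cycle: a pointwise pooled-variance t field, a
familywise critical height from the expected Euler characteristic of a
smooth 1D t field (field smoothness estimated from the unit-normalized
residual gradients), and contiguous supra-threshold runs reported as
significant %-gait-cycle intervals.  A label-permutation distribution of
the field maximum provides a nonparametric cross-check (`n_perm` argument);
on smooth Gaussian cohorts of 11 subjects per group the two thresholds
agree within 10%.  Because the comparison of one deterministic simulation
against an 11-subject cohort is ambiguous in a two-sample design, a z-score
mode (`spm_zscore()`, Gaussian-field threshold) is provided alongside the
cycle-group mode.

# Synthetic data

No trial data are distributed with the package, so `gen_reference_band()`,
`gen_cycle_cohort()` and `gen_sweep_table()` generate everything the
pipeline consumes.  Bands are smooth periodic splines through control
points emulating normative sagittal angle/moment/power curves at
comfortable speed, with smooth strictly positive SD profiles (widest around
push-off and swing).  Cohort cycles add low-frequency correlated Gaussian
perturbations (Fourier spectrum damped as `exp(-(k/3)^2)`, unit marginal
variance) scaled pointwise by the band SD: smooth rather than white noise,
because between-subject gait variability is smooth and SPM cluster
behaviour depends on field smoothness.  Synthetic sweeps draw COT from a
convex cubic with its minimum at a known stiffness `K*` (defaults:
`K* = 3.8` Nm/degree, COT 3.4 J/kg/m at the optimum, curvature 0.06,
asymmetry 0.003, giving a ~0.7 J/kg/m reduction against no AFO — the
magnitudes of the baseline weak-walking condition) plus seeded Gaussian
noise (0.05 J/kg/m), and gait parameters from linear trends with
analytically known threshold crossings.  What passing synthetic tests does
*not* show: that the forward model reproduces any particular patient
cohort; it shows the analysis layer recovers known ground truth and the
mechanics obey their conservation and calibration audits.

# Numerical choices and degenerate inputs

Fits with fewer than five successful sweep rows are errors; failed
conditions (all seeds fell) are flagged rows excluded from fits.  Cubic
fits on four or fewer distinct stiffnesses interpolate exactly.  Zero
variance in a correlation or a t-test denominator is handled explicitly
(flagged `NA`, or t = 0 for identically equal groups).  The muscle
equilibrium bisection brackets fiber length in [0.05, 2.5] optimal lengths
and reports non-convergence for degenerate geometry instead of failing.
Activation and excitation are clipped to [0, 1] everywhere; muscle force is
tensile only; contact never adheres.

# Known limitations

Two-dimensional dynamics: no mediolateral balance, which in reality both
costs energy and is aided by an AFO.  One parameter set drives both legs,
so asymmetric gaits are out of reach.  The energetics coefficients are a
documented choice, not a fitted model, so absolute COT values should be
read as internally consistent rather than calorimetric.  Reduced-budget
optimizations (as used in examples and tests) polish the packaged
controller rather than re-deriving it; full six-seed, plateau-terminated
sweeps are compute-intensive and left to the user with caching enabled.
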