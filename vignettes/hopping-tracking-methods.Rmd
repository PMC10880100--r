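---
title: "Tracking simulations of body-weight-supported hopping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking simulations of body-weight-supported hopping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hopsim estimates internal musculoskeletal loading — muscle forces and joint
reaction forces — during single-leg hopping under body-weight support, and
converts the resulting quadriceps force profiles into hypothetical training
volumes through a muscle-adaptation model. This vignette is the package's
account of the science: the models, their assumptions, the parameters that
matter, and the choices made where the design was genuinely open. All
quantitative statements about accuracy refer to quantities the test suite or
`scripts/acceptance.R` computes.

## The study the package emulates

A harness applies a constant upward force at the pelvis equal to the
offloaded fraction of body weight, so hopping at gravity levels of 0.17,
0.25, 0.37, 0.50 and 1 g can be emulated in a terrestrial laboratory. The
participant hops at a metronome-paced 2 Hz; joint kinematics, ground
reaction forces (GRF) and the support force are recorded; and a
data-tracking optimal control problem (OCP) distributes the measured joint
moments over the model's muscles, from which joint reaction forces and
quadriceps force profiles follow. No motion-capture recordings ship with the
package, so a synthetic-data module generates trials with the study's
structure (five gravity conditions, ~2 Hz hopping, per-condition contact
times between 0.27 and 0.34 s, measurement noise), and the whole pipeline is
exercised against them.

## The planar musculoskeletal model

The model is a sagittal-plane, five-segment rigid-body tree: a pelvis root
(two translations and a tilt), a torso attached by a lumbar joint, and a
thigh-shank-foot chain for the hopping leg (hip, knee, ankle). The
contralateral, flexed leg is lumped into the pelvis segment; masses sum to
the participant's 79.9 kg. Seven generalized coordinates in total: the three
pelvis (root) coordinates carry no actuation, so their inverse-dynamics
entries are residuals that a consistent solution must drive to zero.

Ten Hill-type muscle-tendon units (MTUs) actuate hip, knee and ankle:
iliopsoas, lumped glutei, rectus femoris, the three vasti, lumped
hamstrings, gastrocnemius, soleus and tibialis anterior. The vasti are kept
separate so the rectus-femoris/vasti decomposition of the quadriceps force
can be analysed. The lumbar joint is driven by an idealised torque actuator
(torque = activation x maximum torque) with first-order excitation dynamics
and a 35 ms electromechanical delay.

Muscle paths are straight-line via-point chains fixed in segment frames,
which keeps an exact length function available as a test oracle. The knee
extensors carry a distal-thigh via point that acts as a patellar pulley;
without it the straight-line knee moment arm collapses below 1 cm (and
eventually inverts) at deep flexion, which starves the model of knee
strength exactly where the 1 g hopping task needs it most. Maximum isometric
forces are physiological-cross-section based values for a strong 80 kg
adult (quadriceps total 13.4 kN, soleus 7 kN); they were set, before any
acceptance evaluation, from a static capacity-versus-demand audit of the
synthetic task — a model that cannot produce the moments its own data
demand degrades into kinematic distortion, the well-known signature of
tracking with an unscaled, too-weak musculoskeletal model.

### Muscle-tendon dynamics

Force generation uses dimensionless curves: a three-Gaussian active
force-length curve, a logarithmic force-velocity curve, exponential passive
and tendon curves. The active and force-velocity curves are normalised so
that `f_act(1) = f_v(0) = 1` exactly. The tendon curve's offset is tied to
its stiffness parameter so the tendon force is zero at zero strain, and the
stiffness is calibrated so the normalised tendon force-length slope is 35
at 4% strain (the calibration root is unique because the slope is strictly
increasing in the stiffness parameter). Maximum shortening velocity is ten
optimal fibre lengths per second. Pennation uses the fixed-height model. A
small fibre damping term (0.1 x normalised fibre velocity) keeps the force
balance well-posed at zero activation.

The muscle state is (activation, normalised tendon force); their time
derivatives are controls, and the Hill equilibrium — tendon force equals
the pennation-projected fibre force — is imposed as an algebraic path
constraint (the implicit formulation). Activation rates are bounded by the
two linear inequalities implied by first-order excitation-activation
dynamics with excitation in [0, 1] and time constants t_a = 0.015 s,
t_d = 0.06 s.

### Foot-ground contact

Two spheres (heel and toe, radius 0.02 m) interact with the ground through
a smoothed Hunt-Crossley law: the penetration enters through a smooth
positive part (scale 1e-4 m), the force is `k d^{3/2} (1 + 3/2 c v)`, and a
second smooth positive part (scale 1e-4 N) keeps it non-negative, so the
force is infinitely differentiable everywhere and below a millinewton out
of contact. Tangential force is smooth Coulomb friction,
`-mu F_n tanh(v_slip / 0.05)` with mu = 0.8. Stiffness and damping (shared
across spheres) and the sphere positions are optimised parameters of the
tracking problem; positions may move 5 cm along the sole but only 2 cm
vertically, because larger vertical shifts simply disable a sphere, and
stiffness is bounded to the physical decade 1e5-1e7 N/m^2 (an unbounded
stiffness lets the optimiser park the contact in a quasi-rigid corner where
single mesh points can skip contact entirely).

### Muscle geometry as polynomials

MTU lengths are fitted as multivariate polynomials of the spanned joint
angles (ordinary least squares on 2000 uniformly sampled poses over the
range of motion widened by 20%); moment arms are the negative analytic
partial derivatives of the fitted length, so the moment-arm/length-derivative
identity holds exactly by construction, and lengthening velocity is the
chain-rule contraction with the joint velocities. The shipped model fits at
total degree 6: the patellar-pulley geometry has more curvature than the
degree-4 default of the fitting routine resolves (held-out moment-arm error
8 mm at degree 4 versus 4 mm at degree 6).

## Preprocessing

Raw trials carry kinematics at 200 Hz and force channels at 2000 Hz. All
streams are filtered at 6 Hz with a zero-phase (forward-backward)
second-order Butterworth filter — zero-phase so that touchdown timing is
not shifted; the effective magnitude response is the squared single-pass
response. Filtering precedes cropping so start-up transients stay outside
the analysis window. The analysis window spans 0.15 s before a touchdown to
0.15 s after the next (touchdowns are rising crossings of the vertical GRF
through 10 N; the first pair with full margins inside the record is used).
Interpolating cubic splines built on the full filtered record supply
positions, velocities and accelerations on the 51-point collocation mesh
(spline end-condition artifacts concentrate in the outermost intervals, so
the splines are never evaluated at the record ends). Net joint moments then
follow from inverse dynamics of the resampled streams, with the pelvis rows
reported as experimental residuals.

## The tracking optimal control problem

States are coordinates, coordinate velocities, muscle activations,
normalised tendon forces and the torque-actuator activation; controls are
the state derivatives (implicit dynamics), GRF controls, the actuator
excitation and reserve actuators at hip, knee and ankle; parameters are the
contact stiffness, damping and sphere positions. The cost is
`J = J_effort + J_tracking + J_control` with weights w = (0.01, 1, 10):
volume-weighted squared activations; scaled squared tracking errors of
rotations (2 degrees), translations (0.02 m), GRFs ([5.1, 50] N for
horizontal/vertical) and net joint moments (28.6 N m); and bound-scaled
control regularisation with the reserve scale 2. The moment and force
scales derive from the work principle (the moment or force performing 1 J
over the corresponding kinematic scale; horizontal force scales divided by
gravity). Moment tracking is applied to raw moments in newton-metres —
the scale 28.6 N m is itself a raw-moment quantity — while all reporting
is mass-normalised; a configuration switch restores fully mass-normalised
tracking, which weakens moment tracking by the square of the body mass and
measurably degrades moment reproduction.

Transcription uses Legendre-Gauss-Radau collocation: 50 equal mesh
intervals, third-order state polynomials through four points per interval
(the interval start plus three right-Radau points, the last of which is the
next mesh point). Because state derivatives are controls, every collocation
equation is linear; all nonlinearity is concentrated in path constraints at
the 50 interval-end mesh points: Hill equilibrium per muscle, consistency
of inverse dynamics with muscle moments plus reserves (and with the torque
actuator at the lumbar joint), zero pelvis residuals, and equality of the
GRF controls with the contact-model force. Activation-rate inequalities are
linear. All design variables are affinely scaled to [-1, 1]. Two initial
guesses are constructed: a data-informed guess copying experimental
kinematics and GRFs with remaining variables at their lower bounds, and a
cold guess of zeros (or lower bounds where bounds exclude zero); both share
contact-parameter guesses of 1e6 N/m^2, 2 s/m and the anatomical sphere
positions. The solution with the lower cost among converged runs is kept,
ties resolving to the data-informed guess.

### The solver

The transcribed problem is solved by an augmented-Lagrangian method whose
inner subproblems exploit the structure end to end: the objective is
quadratic (diagonal Hessian) except for the moment-tracking term; the
collocation system is a constant sparse matrix; the path constraints are
separable per mesh point, so their Jacobian is evaluated blockwise in
compiled code (forward differences against a single baseline). Inner
subproblems are minimised by a projected, Levenberg-damped Gauss-Newton
iteration: the Gauss-Newton Hessian is assembled sparsely, bound-fixed
variables are pinned by a large diagonal penalty (keeping the sparsity
pattern constant so the symbolic Cholesky analysis is computed once and
only refactorised numerically), and an Armijo backtracking line search with
step memory handles the stiff contact curvature. Outer iterations update
the multipliers and raise the penalty (factor 2.5) only when feasibility
stalls. Defaults: feasibility tolerance 1e-5 on scaled constraints
(constraint rows are scaled by 500 N for forces and 100 N m for moments),
optimality tolerance 1e-4, at most 40 outer rounds of at most 25
Gauss-Newton steps. A run that makes no feasibility progress over six outer
rounds is declared stalled — in practice the data-informed guess converges
and the cold guess stalls at a higher cost, so the selection rule picks the
data-informed solution.

## The synthetic-data generator

The generator's defaults are the study conditions: gravity levels
{0.17, 0.25, 0.37, 0.50, 1.0}, 2 Hz hopping, per-condition contact times
(0.29, 0.27, 0.28, 0.32, 0.34 s), participant mass 79.9 kg and height
1.82 m, five trials per condition, measurement noise of 0.5 degrees on
joint angles (2 mm on pelvis translations) and 5 N on force channels. The
true contact parameters behind the synthetic GRFs are 2e6 N/m^2 and
0.2 s/m; the damping is deliberately low because beyond roughly 0.7 s/m the
Hunt-Crossley unloading factor can null the contact force, and the
generator's contact-law inversion (below) then loses its root.

A trial is built to be as dynamically consistent as a template-based
construction allows:

* the vertical GRF is prescribed as a raised-cosine pulse over stance whose
  impulse exactly balances the offloaded weight over the cycle; double
  integration of the implied centre-of-mass acceleration gives a periodic
  com-height path that is pointwise consistent with that force by
  construction;
* hip and knee flexion bumps (raised-cosine over stance) grow with gravity
  — modestly across the hypogravity range and steeply towards 1 g — which
  reproduces the ankle-dominant-to-whole-limb strategy shift; the foot
  keeps a constant, slightly plantarflexed pitch (forefoot hopping), so
  only the toe sphere bears load and the contact point neither sweeps nor
  slips (the ankle dorsiflexion pattern then emerges from the hip and knee
  angles);
* per sample, a hip correction keeps the whole-body centre of mass exactly
  above the toe sphere (Newton on a near-linear geometry residual) and a
  knee correction places the foot at the depth where the contact model
  reproduces the prescribed GRF (safeguarded bisection on a relation made
  monotone by counter-rotating the ankle); corrections blend through flight
  with a C1 Hermite arc;
* an outer pass nulls the angular-momentum (pelvis-tilt row) residual by a
  Newton update of the lumbar (torso counter-swing) path through the exact
  joint-space mass-matrix entry — the lumbar joint is outside the leg
  chain, so this does not disturb the contact solves.

The remaining inconsistency — what the OCP's zero-residual constraint must
absorb — is below 5 N vertically and horizontally and below 40 N m in tilt
at every gravity level (measured by the generator's own diagnostics and
asserted in the tests). Trial-to-trial variability is a seeded 3% jitter on
the template amplitudes. What the generator does not emulate: marker-level
noise and soft-tissue artefact, asymmetric or non-periodic hops, harness
force fluctuations (an idealised constant support force is used), and any
muscle-driven origin of the motion — activations are not part of the data,
so tests of the pipeline say nothing about the physiological realism of
recovered activation patterns on real recordings.

## Analysis

Tracking quality is reported as maximum and RMS errors per channel group
(rotations in degrees, translations in metres with and without the pelvis
vertical channel, GRFs in body weight, moments in N m/kg), and a solution
is accepted only if no reserve actuator exceeds 5 N m or 10% of the
corresponding net joint moment (the percentage read against moments larger
than 5 N m, where the ratio is meaningful). Joint reaction forces are
computed by applying every muscle's tendon force as a pair of point forces
at its end attachments, the optimised contact forces and the support force
as external loads, and reading the intersegmental force from a recursive
Newton-Euler pass; the reported component is the force along the child
segment's long axis (for the knee: the force applied to the tibia by the
femur, compression positive), with a switch for the lab-frame vertical
component. Peaks and impulses (trapezoidal integrals over one
touchdown-to-touchdown cycle) are normalised to the 1 g body weight.

## The adaptation model

Quadriceps loading drives a cross-sectional-area (CSA) model:
`dCSA/dt = (1/tau) (CSA_max - CSA)/(CSA_max - 1) delta max(F - F0, 0)`,
with CSA normalised to baseline, F the cumulative active-plus-passive force
of the four knee extensors normalised to their summed maximum isometric
force, and F0 = 0.2 (20% of one-repetition maximum). The drive is clamped
at zero — the model grows only — and the state saturates at CSA_max. The
model is separable: with Phi(t) the cumulative supra-threshold drive,
`CSA = CSA_max - (CSA_max - 1) exp(-delta Phi / (tau (CSA_max - 1)))`,
which supplies the closed-form oracle used in the tests and the exact
per-repetition recursion used to find the smallest repetition count
reaching a target. Numerical integration (adaptive ODE stepping) is the
reference implementation and agrees with the closed form to 1e-6.

Only delta/tau is identified by behaviour, so calibration fixes delta = 1
and solves for tau from a documented synthetic reference: a constant
normalised force of 0.75 held 3 s per repetition reaches the minimal
worthwhile CSA increase of 3.37% after 108 repetitions (nine 12-repetition
sets, the midpoint of a 6-12 set fortnight at 3 sessions per week, which is
the regime heavy-resistance training programmes report). CSA_max is 1.2
(a 20% ceiling). Training volumes divide the required repetitions by 12
per set and 3 sessions per week, rounding up. Absolute repetition counts
from synthetic data are not comparable to any participant's values; the
model's use is comparative across loading conditions. With the shipped
model's strength (set by the 1 g task), normalised quadriceps loading in
deep hypogravity falls below the 0.2 threshold altogether, and the volume
is then reported as infeasible — the limiting case of hypogravity hopping
being an impractical hypertrophy stimulus. Rest between
repetitions and sessions is not modelled; parameters calibrated against
whole training programmes absorb it implicitly.

## Numerical choices and degenerate inputs

* Collocation path constraints are imposed at the 50 interval-end mesh
  points (where derivative controls exist); the initial mesh point carries
  only the dynamics and bounds.
* Tracking integrals use trapezoidal weights on the mesh for mesh-point
  quantities and Radau quadrature for collocation-node quantities (effort
  and rate regularisation).
* The actuator excitation is discretised at the collocation nodes so that
  an exactly feasible point exists for polynomial test trajectories.
* Ties between converged initial guesses resolve to the data-informed one.
* Touchdown detection interpolates the threshold crossing linearly between
  samples; trials whose GRF never crosses the threshold twice are rejected
  with the threshold in the message.
* Infeasible adaptation targets (profile never above threshold, target
  above the ceiling) return an explicit infeasible result, not an error.
* The problem sizes used by the shipped experiments — 50 mesh intervals,
  one trial per condition, 2000 fitting poses — are the package's default
  study scale; every reported quantity is recomputed at run time at that
  scale.

## Known limitations

The model is planar and single-legged; bilateral coordination, frontal- and
transverse-plane mechanics and wrapping muscle geometry are out of scope.
Contact parameters other than stiffness are weakly identified by tracking
alone: stiffness recovery within 20% is demonstrated in a dedicated
identifiability experiment with tightly tracked translations and fixed
sphere positions, but damping recovers poorly, and in the standard
experiment the optimised stiffness should be read as a nuisance parameter.
The adaptation model represents mechanical-tension-driven hypertrophy only.
The augmented-Lagrangian solver is first-order in the multipliers; its cold
(all-zero) initial guess regularly stalls where an interior-point method
with exact second derivatives might converge, which the two-guess protocol
absorbs by selection.
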