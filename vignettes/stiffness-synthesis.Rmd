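---
title: "Endpoint stiffness synthesis, muscle synergies, and energy flexibility in a planar arm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endpoint stiffness synthesis, muscle synergies, and energy flexibility in a planar arm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiffarm)
```

## The model

`stiffarm` analyzes how much a tendon-driven planar limb can control the
*endpoint stiffness* of its hand — the symmetric 2×2 matrix $K_{end}$
relating a small hand displacement to the restoring force it evokes — and
how much freedom remains, once a stiffness is prescribed, to economize on
muscular effort.

The nominal system is a two-link arm with unit link lengths and six
muscles: a mono-articular antagonist pair at the shoulder, one at the
elbow, and a bi-articular pair crossing both joints with same-sign moment
arms (human arms have no bi-articular muscles that flex one joint while
extending the other). Moment arms have unit magnitude, maximal muscle
forces are one, and the muscle stiffness-per-force scale $\alpha$ is one,
so all quantities are in consistent model units. The chain of mechanics
is:

$$k_i = \alpha\, F_{max,i}\, a_i, \qquad
  K_{joint} = R\,\mathrm{diag}(k)\,R^\top, \qquad
  K_{end} = J^{-\top} K_{joint} J^{-1},$$

with $a \in [0,1]^M$ the neural activation vector, $R$ the joints×muscles
moment-arm matrix (torque $= R F$), and $J$ the posture-dependent
manipulator Jacobian. Active stiffness only: no passive tissue, no
reflexes, no external endpoint force, so $K_{end}$ is exactly symmetric
and positive semidefinite for any nonnegative activation.

A stiffness matrix is summarized as an ellipse: **size** (trace),
**shape** (condition number, major/minor eigenvalue ratio), and
**orientation** (major-axis angle from the x-axis, degrees on the
180°-periodic axis). The eigendecomposition of a symmetric PSD matrix
coincides with its SVD, so either wording describes the same extraction.
When the two eigenvalues agree to within a relative tolerance of $10^{-9}$
the matrix is isotropic and the orientation is reported as undefined
(`NA`) rather than as an arbitrary angle.

## Realizability as line–box geometry

Since every step above is linear in $a$, the three independent entries of
$K_{end}$ are a fixed linear image of the activations:
`stiffness_linear_map()` returns the 3×M operator $M$ with
$\tilde K_{end} = M a$, whose column $i$ is the vectorized rank-one
stiffness contribution of muscle $i$. A task then imposes five equality
constraints on six activations:

* torque equilibrium, $R\,F_{max}\,a = 0$ (2 rows, zero right-hand side);
* the desired stiffness, $M a = \tilde K_{end,desired}$ (3 rows).

Generically the solution set is a line in activation space; intersected
with the box $[0,1]^6$ it is a segment — the *feasible activation set*.
`feasible_segment()` computes it exactly (SVD rank, minimum-norm
particular solution, null direction, per-coordinate interval
intersection) instead of trusting an optimizer's status code, which gives
a sharp realizability boundary and an honest emptiness test. Tolerances:
equality-consistency residual $10^{-8}$ (relative), box slack $10^{-9}$,
SVD-based machine rank tolerance; all are arguments.

Non-generic systems (duplicated muscles, extra muscles) can leave a null
space of dimension ≥ 2. The segment parametrization then does not apply;
the package flags the case and falls back to quadratic programming for
feasibility and energy minimization and to exhaustive vertex enumeration
(fix null-dimension-many coordinates at a bound, solve, filter) for the
energy maximum, which is attained at a vertex because the energy is
convex.

**Scale freedom.** Whether a (shape, orientation) pair is realizable at
*some* positive size is scale-free: the equality right-hand side is
homogeneous in the desired size, the lower bounds $a \ge 0$ form a cone,
and the upper bounds only relax as the size shrinks. `is_realizable(...,
scale = "auto")` therefore intersects the solution line with the
nonnegative orthant only. When a concrete size is needed (energy
analyses), `auto_scale()` picks one that places the segment's endpoints
at a maximum activation of 0.5, comfortably below saturation; the paper
trail for this choice is that the energy-reduction ratio below is
invariant to the size as long as the upper bounds stay inactive, so any
sub-saturation size reports the same reduction (a property the test suite
checks at two scales).

## Energy and its feasible range

The effort surrogate is the sum of squared muscle forces,
$E(a) = \sum_k (F_{max,k} a_k)^2$. Along the segment
$a(t) = a_0 + t\,d$ this is a 1-D convex parabola, so the minimum is the
clamped vertex and the maximum sits at a segment endpoint —
`min_energy()` and `max_energy()` are exact, with an independent QP
solver and a dense-grid sampler (`oracle_energy_bracket()`) used as
cross-checks in the tests, never as the implementation. The headline
statistic is the *maximal possible energy reduction*
$100\,(E_{max}-E_{min})/E_{max}$: when it is near zero, observing the
stiffness ellipse already pins down the energetic state; when it is
large, the nervous system has genuine room to economize.

The three-muscle single-joint limb (`single_joint_arm()`, moment arms
$(1, 2, -1)$) is the smallest system where this geometry is visible: one
torque row and one stiffness row leave the segment
$a(t) = (0.5 - 3t,\; t,\; 0.5 - t)$, $t \in [0, 1/6]$, for unit desired
joint stiffness, with $E(t) = 11t^2 - 4t + 0.5$, $E_{min} = 5/36$ at
$t = 1/6$ (the unconstrained vertex $t = 2/11$ lies outside the segment)
and $E_{max} = 1/2$ at $t = 0$ — a 72.2% possible reduction. These
closed-form values anchor the test suite.

## Synergies as constraints

A muscle synergy is modeled prescriptively: a nonnegative muscles×synergies
weight matrix $W$ restricts activations to $a = W c$, $c \ge 0$. The
built-in `osu_gomi_basis()` encodes the two synergies reported in EMG
studies of static arm co-contraction: a shoulder synergy driving both
mono-articular shoulder muscles with unit weight, and an elbow synergy
driving the mono-articular elbow muscles with unit weight and the
bi-articular pair with weight 0.5. Both synergy columns are
torque-balanced on the symmetric arm, so every command is automatically in
equilibrium, and a single free parameter — the elbow/shoulder activation
ratio — controls the ellipse's shape *and* orientation jointly; scaling
both commands together changes only its size.

`ratio_sweep()` sweeps that ratio (default 200 log-spaced values in
$[0.1, 10]$; the orientation range moves by under a degree when the
density is doubled, which the tests verify) with commands normalized to
$c_s + c_e = 0.5$ — any sub-saturation normalization gives the same
shape/orientation path. `orientation_range()` reports the circular range
on the 180°-periodic axis as 180° minus the largest empty arc. At the
posture with the hand at $(0, 1)$ (elbow-positive branch, shoulder 30°,
elbow 120°) the sweep covers ≈ 71.8°, a realizable fraction of ≈ 0.399 of
all orientations — versus 1.0 for moderate shapes without synergies at the
same posture. `constrained_realizability()` runs the same feasibility
logic in command space for arbitrary bases and reports the solution-space
dimension (the three-muscle example with the tie $a_1 = 2a_2$ collapses to
a unique solution).

## Workspace maps and study conditions

`realizable_fraction_map()`, `energy_reduction_map()` and
`synergy_fraction_map()` evaluate these quantities on a joint-angle grid
(default 25×25) over the workspace, with orientation tested every 5° (36
angles over 180°). Default joint limits are shoulder $[0°, 160°]$, elbow
$[5°, 175°]$ — a plausible human planar workspace that excludes the
Jacobian singularities; the source analyses defer their exact limits to
earlier work without restating them, so these are this package's own
documented choice. Maps are computed and stored in joint space with
endpoint coordinates attached, avoiding inverse-kinematics branch
ambiguity; reduction maps aggregate by the maximum over realizable
orientations (the natural reading of "greatest possible reduction for any
orientation"). With these conditions the workspace-wide maximum reduction
at the manifold shape for ratio 1 (condition number 1.5) is ≈ 48%, with
typical values in the 10–30% band and black "no-room" regions where the
feasible set degenerates to points.

Two empirical subtleties the analysis surfaced, both verified against an
independent brute-force sample of the achievable stiffness cone:

* **Monotonicity in eccentricity is conditional.** Wherever the isotropic
  ellipse is realizable, the realizable orientation set shrinks as the
  condition number grows — an ellipse of smaller eccentricity at the same
  angle is a conic combination of the more eccentric one and the identity,
  and the achievable stiffnesses form a convex cone. At postures where the
  circle is *not* realizable the trend can reverse (highly eccentric
  ellipses realizable where round ones are not). Tests assert monotonicity
  only on circle-realizable postures.
* **Very eccentric shapes fragment.** At the $(0,1)$ posture the synergy
  manifold's shape at ratio 0.1 has condition number ≈ 9.27; without
  synergies, only three isolated 5°-grid orientations (near 30°, 90°,
  150°) admit that exact shape, so the per-shape realizable fractions at
  the three manifold anchor shapes are (0.083, 1, 1) rather than all 1.
  Mild shapes (≲ 3 at this posture) are realizable at every orientation.

## What the generator does and does not emulate

All inputs are model parameters; there is no external data. The randomized
arms (`random_arm()`) draw moment-arm magnitudes uniformly from
$\pm[0.3, 1.5]$ — bounded away from zero to avoid near-singular test
systems — and are rejection-sampled to guarantee antagonist coverage per
joint, full row rank, and a strictly interior equilibrium activation.
They exercise the algebra (the linear-map identity, rank counting,
segment-vs-QP agreement) but are not anatomical: real limbs have unequal,
posture-dependent moment arms, muscle force–length/velocity properties,
passive and reflexive stiffness, and noise, none of which is modeled.
Passing tests therefore certify the geometry and optimization machinery
and the qualitative synergy conclusions, not physiological magnitudes.

## Numerical choices, in one place

* Angles: radians in the R API for postures, degrees for ellipse
  orientations (the field's reporting convention) and in config files.
* Vectorization order of symmetric matrices is $(K_{xx}, K_{xy}, K_{yy})$;
  any consistent order gives identical results.
* Problem sizes in the shipped analyses: 200-point ratio sweeps, 36
  orientation tests per posture, 25×25 workspace grids, 100-posture rank
  audits, 1000-system linear-map equivalence sweeps.
* Ties and degeneracies: isotropic matrices report `NA` orientation;
  `orientation_range()` of a single point is 0°; unrealizable tasks are
  results (`status = "unrealizable"`), never errors; degenerate null
  spaces are flagged and handled by the QP/vertex fallback.

## Known limitations

Static postures only — no movement, no dynamics, no signal-dependent
noise. Two joints; the linear-map construction generalizes but only the
planar Jacobian is implemented. The energy surrogate is the standard
sum-of-squared forces, which ignores activation-rate and heat terms. The
exact workspace limits and the desired-stiffness sizes of the original
analyses are not recoverable from their description; both are explicit,
overridable parameters here, and the scale-invariance of the reported
ratios makes the size choice immaterial below saturation.
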