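---
title: "Designing focal-deep TMS coils in a spherical head model"
author: "focalcoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing focal-deep TMS coils in a spherical head model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transcranial magnetic stimulation (TMS) coils induce an electric field in the
brain by magnetic induction. Conventional figure-8 coils trade focality for
depth poorly: a field that reaches a deep target also stimulates a large
superficial volume. focalcoil implements a design pipeline for focal-deep
coils: it optimizes a continuous surface current on a parametric coil former
for minimum stored magnetic energy under constraints that shape the
stimulated region, then converts that current into a manufacturable wire
winding, and finally evaluates depth, spread, energy, inductance and scalp
exposure of the result.

## Model components and assumptions

### Surface currents on a coil support

The coil former is a triangle mesh $\Omega$. Divergence-free surface currents
are parametrized by a stream function $Sr(\mathbf r, \lambda) = \sum_i
\lambda_i N_i(\mathbf r)$ over linear nodal elements, with $\lambda_i$
attached to the internal (non-boundary) nodes so that $Sr$ vanishes on the
open boundary and every isocontour closes. The current density is
$\mathbf I = -\hat{\mathbf n} \times \nabla Sr$: piecewise constant per
triangle, tangential, and discretely divergence-free (the current crossing
any interior edge equals the difference of the nodal stream values, computed
consistently from both sides).

Four support shapes are generated parametrically: a flat square, a sphere, a
half-sphere, and a "hat" (a spherical-cap crown blended C1 into a flaring
annular brim). The hat stands in for head-conformal formers derived from
anatomical imaging: it is an approximation with two parameters (crown radius,
brim width, with the crown extent fixed at a 45-degree polar angle), not a
reconstruction of any published former. The closed sphere has no boundary;
its lowest vertex is designated the stream-function gauge node.

### The induced field in the two-sphere head model

The head model is two concentric spheres (brain radius 0.070 m, outer radius
0.085 m). In the quasi-static regime a spherical conductor carries no radial
induced current, and the interior field is independent of both the
conductivity and the sphere radius. For an external current element
$I\,d\mathbf l$ at $\mathbf q$ the induced field at an interior point
$\mathbf r$ has the closed form

$$
\mathbf E(\mathbf r) = -\frac{\mu_0 \dot I}{4\pi}\left[
\frac{d\mathbf l}{a} - G(\mathbf r)\, d\mathbf l -
(\mathbf r \cdot d\mathbf l)\, \nabla G(\mathbf r)\right],
\qquad
G(\mathbf r) = \int_0^1 \frac{dt}{\|t \mathbf r - \mathbf q\|},
$$

with $a = \|\mathbf r - \mathbf q\|$ and $G$ evaluated by logarithmic
expressions chosen per the sign of $\cos\angle(\mathbf r, \mathbf q)$ to
avoid cancellation. The charge term cancels the radial component exactly at
every interior point, which the tests assert to $10^{-10}$ relative. The
implementation is validated against an independent Gauss-Legendre quadrature
of the same boundary-value construction and against the exact free-space
field for axisymmetric sources (for which the charge contribution vanishes).
Each mesh triangle's constant current is represented by three edge-midpoint
current elements; wire polylines are subdivided to at most 2 mm segments.
Reported fields are amplitudes at the peak of the sinusoidal drive
$p(t) = \sin(\omega t)$, $\omega = 2\pi \cdot 3000$ rad/s.

### Figures of merit

With target field $E_{\mathrm{targ}}$ at the target depth (the absolute value
is a convention; the package default is 100 V/m and all energies scale with
its square):

* stimulated volume $V$: brain volume with $\|\mathbf E\| \ge$ threshold,
  on a Cartesian voxel grid (ties stimulated);
* stimulation depth $d_M$: deepest point on the coil axis where the
  directional component $\mathbf E \cdot \hat{\mathbf t}$ meets the
  threshold (linear interpolation at the crossing);
* spread $S = V / d_M$;
* half-maximum metrics $V_{1/\alpha}, d_{1/\alpha}, S_{1/\alpha}$: threshold
  at the peak brain field divided by $\alpha$, hence scale-independent. The
  peak reference uses the field magnitude (with a dedicated cortical-surface
  sample, since the peak sits on the brain surface between voxel centers);
  the depth criterion uses the directional component, with a configuration
  switch to use the magnitude for sensitivity checks;
* stored magnetic energy $W(\lambda) = \lambda^T W \lambda$ from the
  Biot-Savart double surface integral, assembled per triangle pair with an
  analytic inner (single-layer potential) integral and a 3-point interior
  outer rule, singularity-safe for self and adjacent pairs;
* depth-swept curves $V_d, S_d, W_d$: the drive is rescaled per target depth,
  depths whose scaling pushes the peak brain field above
  $\alpha E_{\mathrm{targ}}$ are marked unreachable;
* scalp metrics: outer-sphere area above $E_{\mathrm{targ}}$ and the peak
  scalp field ratio.

## The design optimization

The designer minimizes $\lambda^T W \lambda$ subject to linear constraints on
the field. Field-magnitude bounds $\|\mathbf E\| \le b$ are imposed as 16
half-plane constraints in the tangent plane of each constrained point (the
field has no radial component, so the constraint is two-dimensional); the
16-gon is edge-tangent, so feasible fields are certified to satisfy
$\|\mathbf E\| \le b / \cos(\pi/16)$. Constraints are activated lazily:
points enter the active-set QP only when violated, keeping the solve small.
The QP itself is a minimum-norm problem in an energy-whitened mode basis
(generalized eigenvectors of the field Gram matrix against $W$, 250 modes by
default), solved by a primal active-set method with rank-revealing SVD
solves. `pracma::quadprog` is used in the tests as an independent
cross-check, never as the implementation.

Two equalities pin the field profile: $\mathbf E \cdot \hat{\mathbf t} =
E_{\mathrm{targ}}$ at the target depth, and $\mathbf E \cdot \hat{\mathbf t}
= \alpha E_{\mathrm{targ}}$ at the cortical point nearest the coil. The
second pin was a deliberate design choice: the energy-minimal current
otherwise leaves the peak-field cap slack, so the half-maximum threshold
falls below the focality bound and the half-maximum region spills beyond the
candidate region, inflating $S_{1/2}$ and overshooting the depth target.

The candidate stimulated region is an elliptical cylinder around the depth
line, elongated along the target direction (the
$\mathbf E \cdot \hat{\mathbf t}$ footprint of any figure-8-like coil is
elongated along $\hat{\mathbf t}$; we measured that circular cylinders are
infeasible below about 30 mm radius on the hat support and cap the
achievable spread well above the values the elliptical family reaches).
Outside the region the field magnitude is bounded by $E_{\mathrm{targ}}$,
inside by $\alpha E_{\mathrm{targ}}$. An optional greedy refinement then
shrinks the admissible region (lowest-field samples first, protecting a core
cylinder) while the energy stays within the budget - a sequential convex
approximation of direct volume minimization. The Pareto sweep solves this
design over a grid of region shapes and reports the non-dominated
energy/spread curve; `design_for_target` selects the most focal design
within the energy budget (200 J by default).

The wire-fit iteration adds 16-gon bounds on the triangle currents where the
contour spacing implied by the previous iterate would not admit the wire
width ($\max\|\mathbf I\| \le \Delta_{sr}(M) / W_{\mathrm{wire}}$, with
$\Delta_{sr}$ from the previous design), re-solving until satisfied.

## Winding synthesis

Wires are placed on stream-function isocontours (marching triangles, levels
perturbed by $10^{-9}$ of the range when they coincide with a nodal value,
loops oriented along the local current). The surface is partitioned into
sub-coil basins by steepest ascent/descent from every node; the two basins
with the largest absolute extremum form the figure-8 core, and the remaining
basins are biasing (same sign as the nearest core lobe) or cancellation
(opposite sign). Loops are assigned to basins by the majority basin of their
extremum-side nodes.

The hybrid-layer build winds the figure-8 core in three layers and all other
basins in one. Layers are offset along the local surface normal away from
the head by the wire height, innermost loop on the layer closest to the
head, round-robin by concentric order. The number of contour intervals $M$
is the smallest whose (spacing-repaired) winding reaches the 8.8 uH
inductance floor; we measured that larger $M$ only increases the stored
energy, so the minimal admissible $M$ is also the energy-optimal choice.
Uniform levels that violate the 2.2 mm same-layer concentric spacing are
first respaced deterministically within their basin, then thinned if
respacing is insufficient. The contour levels are then optimized
(Nelder-Mead from the uniform start; deterministic, no random restarts) to
minimize

$$
\|\mathbf E_{\mathrm{coil}} - \mathbf E_{\mathrm{ideal}}\|_F +
10^{-5}\,\|\mathbf E_{\mathrm{ideal}}\|_F\, W_{\mathrm{coil}},
$$

where the fields are sampled on a spherical shell (46,532 points at full
scale; smaller counts for tests), the coil drive $s$ is the least-squares
match to the ideal field, and $W_{\mathrm{coil}} = \frac12 L s^2$ with $L$
from the Neumann formula over all segment pairs plus the external partial
self-inductance $\frac{\mu_0 l}{2\pi}(\ln(2l/a) - 1)$ of each straight
segment. Spacing and the inductance floor enter as penalties with a hard
post-check that falls back to the uniform start. Loops are connected
serially with deterministic rules standing in for manual routing: radial
jogs between concentric loops at the azimuth farthest from the coil center,
bridges between families at their closest approach, traversal preserving
each loop's winding sense.

## Numerical choices

* Brain grid: 2 mm for design-stage metrics, 1 mm (with coarse-pass bounding
  box pruning) for final reporting; depth profiles at 0.1 mm.
* Constraint samples: ~1200 cortical plus ~600 interior guard points on the
  hemisphere facing the coil.
* Element quadrature: 3 edge-midpoint elements per triangle (order
  configurable); doubling the wire-segment subdivision changes fields by
  less than 0.01%.
* Solver tolerances: equality feasibility 1e-6 relative; constraint
  activation at bound/cos(pi/16) with 1e-7 headroom; deterministic
  throughout - the pipeline has no random state, and seeds are recorded only
  for provenance.
* Degenerate inputs rejected with messages: zero-extent supports, sliver
  triangles, boundary-node seed currents, open wire loops, points outside
  the conductor, sources within 1 mm of the scalp.

## Reference-scale results and known limitations

At the package's reference problem size (hat support at 7 mm resolution,
~930 internal nodes - chosen so a full two-target run completes in minutes
on one core) the intermediate-depth hybrid design reproduces the expected
spread (S_1/2 ~ 10.7 cm^2), inductance (>= 8.8 uH), spacing (>= 2.2 mm) and
continuous-current energy (164 J within the 200 J budget). Two quantities
fall short of full-scale expectations, for a documented physical reason: the
three-layer figure-8 stack sits 0-6 mm farther from the head than the design
surface, attenuating the deep field by roughly a third. The winding
therefore needs a higher drive than the continuous current (stored energy
~230 J rather than ~160 J) and its half-maximum depth lands ~5% shallow of
the design target (1.24 cm vs 1.31 cm). Closed-loop corrections
(re-designing at a deeper target, or de-rating the design cap by the
measured peak excess) were implemented and found unstable at this scale -
the candidate-region selection jumps discontinuously and the inductance
floor becomes unreachable - so the default pipeline is single-pass
(`max_correct = 0`) and reports the shortfall honestly.

The synthetic-data generator (`make_fixtures`) emulates the geometry of the
problem - a two-loop circular figure-8 reference coil and a stream function
with the canonical 2 figure-8 + 2 biasing + 4 cancellation basin structure -
but not the full complexity of optimized currents (which develop additional
weak basins) nor any anatomical realism. Passing tests demonstrate the
correctness of the geometry, field, energy, optimization and discretization
machinery in the spherical model; they do not certify performance in
realistic heads, where tissue heterogeneity changes the field distribution.
Gray-matter-restricted metrics, realistic-anatomy simulation, coil former
solid modeling, AC resistance, thermal and pulse-circuit behavior, and any
human-subject quantities are out of scope.
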