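---
title: "Planning dynamic arcs with effective-fluence motion modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning dynamic arcs with effective-fluence motion modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`dynarc` plans radiotherapy delivered by a robot-mounted 6 MV linac with a
multileaf collimator (MLC), either as a *dynamic arc* — the beam stays on
while the robot sweeps through control points ("nodes") spaced 5° apart —
or as conventional step-and-shoot beams. All geometry lives in a
right-handed room frame with +z vertical and the target point at the
origin; every node's source sits 800 mm from the target (the nominal
source–axis distance), and each node carries an orthonormal beam's-eye-view
(BEV) frame: `u` along leaf travel, `v` along the leaf-pair stack. Leaves
are paired two-by-two, so the fluence grid has 7.7 mm rows (two 3.85 mm
leaf widths) by 5 mm columns, and apertures are represented at paired-row
resolution throughout; the physical 20-leaf-pair bank is recovered by
duplicating each row on export.

Dose is the linear superposition `D_i = Σ_j d_ij w_j` of per-beamlet
(bixel) influence columns. The vendor dose engine behind the original
machine is proprietary, so the package uses a documented surrogate: a
divergent pencil beam with depth dose `D(d) = (1 − e^{−βd}) e^{−μd}`
(defaults β = 0.14 /mm, μ = 0.005 /mm, giving a ~24 mm build-up maximum),
an inverse-square factor referenced to 800 mm from the source, and lateral
profiles formed by Gaussian-blurred bixel edges (σ = 2.5 mm at the nominal
plane) evaluated in back-projected BEV coordinates. Edge profiles are used
instead of a point Gaussian so that adjacent bixels tile exactly to a flat
field — a property the motion demonstrations rely on. Columns are truncated
at 0.015 % of their own maximum and stored sparsely; the truncation changes
the integral phantom dose by well under 0.1 %. MU calibration is 1 MU =
1 cGy at the build-up maximum at the reference distance; because finished
plans are renormalized to the prescription, this constant only affects
reported MU counts, not any compared dosimetric quantity.

### The three optimization stages

**Fluence.** The objective is quadratic one-sided penalties per structure
(targets get both minimum- and maximum-dose terms, normal tissue only the
maximum term), minimized over non-negative beamlet weights by a projected
L-BFGS: two-loop recursion with 8 stored curvature pairs, projection
`w ← max(w, 0)` after each trial step, and a backtracking Armijo line
search (c = 1e-4, halving, initial step 1/‖∇F‖ on the first iteration, 1
afterwards). The line search accepts only non-increasing objectives, so the
trace is monotone by construction; a failed search contributes a zero step
and the iteration continues. Curvature pairs with non-positive curvature
after projection are discarded. Forty iterations are the default
everywhere. Initial weights are uniform over beamlets with non-empty dose
columns, scaled so the mean target dose matches the minimum-dose level;
this makes the first iterations productive without biasing the result.
Importance rescaling leaves the iterate sequence unchanged (the line search
is scale-adaptive), which the tests assert.

**Sequencing.** Fluence maps are decomposed by the reducing-level
(Xia–Verhey) method: each delivery level is the largest power-of-2
*fraction of the initial map maximum* not exceeding the residual maximum,
and the open region per row is the longest run of above-level columns
(leftmost on ties), so every segment is one interval per row — MLC
deliverable. This fractional-level convention makes a uniform map of any
value a single segment. Exact reconstruction is guaranteed for maps whose
values are dyadic sums with a power-of-2 global maximum and per-level
contiguous threshold sets (e.g. monotone staircase rows); the test suite
uses exactly that family. For arcs, fluence is optimized at every third
node (15°), each map is sequenced into at most three apertures, the
middle-weight one stays at the fluence node and the outer two go to the ±5°
neighbours in the order minimizing summed leaf travel. Step-and-shoot plans
are sequenced greedily under a global aperture budget (default 110): each
step gives the next reducing-level segment to the node whose step removes
the most residual fluence, so nodes may end with zero or several segments.

**Direct aperture optimization (DAO).** Leaf positions and segment MU are
one variable vector driven by the same projected L-BFGS. MU is kept on a
linear scale with projection to MU ≥ 0 rather than a log parameterization:
the machine explicitly allows 0 MU segments and the sequencer produces
them, which a log scale cannot represent. The projection applies the full
machine rule set to every aperture after every trial step, in the order:
close malformed/undersized rows → opposing-leaf rule (gaps under 5 mm to
the opposing leaf of an adjacent row are opened to 5 mm; interdigitating
rows close the narrower pair) → minimum field length → per-interval travel
clip against the previously projected node (arc mode). Because the
opposing-leaf rule and the travel clip can interact, the rules are iterated
to a fixed point (at most 6 sweeps) instead of a single re-check; this
makes the projection idempotent, which the randomized tests verify.

The dose gradient with respect to the beamlet-level fluence is exact and
analytic (`∇_φ F = Dᵀ ∇_D F`); the inner derivative of the per-bixel
fluence with respect to each leaf position is taken by central finite
differences (0.05 mm step) on the one or two fluence rows that leaf
touches. For the static exposure model this derivative is the simple
piecewise-constant `±Φ/w` inside the tip's bixel and is coded analytically;
for the effective-fluence model the exact derivative has many kink cases,
and the row-level finite difference is cheap (a handful of scalar
operations per row), robust, and verified against full finite differences
of the objective. This is a deliberate trade of elegance for reliability.

### Effective fluence of the moving aperture

Between nodes the leaves move at constant speed (no acceleration modeling,
by assumption) while the beam delivers the interval's MU at constant dose
rate. A point `x` is exposed while `L(t) ≤ x ≤ R(t)`; its fluence is the
open-field fluence Φ times the measure of that time set. For leaves moving
in the opening direction this is the familiar ramp difference
`clip[(x−L_init)/(L_fin−L_init) − (x−R_init)/(R_fin−R_init)]`; the
implementation computes the exposure-interval intersection directly, which
also covers leaves moving in either direction and stationary leaves (the
step-function limit), and always satisfies 0 ≤ φ ≤ Φ. Per-bixel values are
the exact average of φ over the bixel width: φ(x) is piecewise linear with
a known, small set of breakpoints (the four leaf endpoints, the crossing of
the two leaf-time lines, and zero crossings of the pre-clip exposure
length), so a midpoint rule on breakpoint-refined segments integrates it
exactly. In the static limit this reproduces the partial-bixel exposure
fraction used everywhere else, and the dense K-aperture interpolation
oracle converges to it at O(1/K), both asserted in the tests. Each
interval's fluence is attributed to the terminal node's beam orientation;
the first node of a trajectory is delivered with its own static shape.

### Recalculation and evaluation

For verification, each interval is re-expanded to 5 interpolated
orientations and 20 interpolated shapes per orientation step (0.05°
effective resolution), with shapes coalesced onto the following
interpolated node and the interval MU split equally among the 100 shapes.
Orientation interpolation uses the full relative rotation between the two
node *frames* (axis-angle of `R_B R_Aᵀ`), not just the beam directions:
interpolating directions alone leaves an in-plane collimator twist wherever
the rotation axis changes (arc junctions), which would evaluate a twisted
copy of each aperture and spoil the very model-consistency comparison the
recalculation exists for. The tests pin this down by checking that a
dense-shape recalculation at the plan's own orientations reproduces the
effective-fluence dose. Interpolated shapes
sample the continuous leaf motion at step midpoints, the unbiased
convention. Aperture shapes interpolate linearly per leaf, consistent with
the constant-speed assumption.

Evaluation reports cumulative DVHs (0.05 Gy bins, D95 by interpolation;
direct percentile oracles in the tests), the conformity index
`CI = (PTV_pres/PTV)(PTV_pres/V_pres)` — maximum 0.95 when plans are
normalized to 95 % coverage — and delivery times: dynamic intervals cost
`max(60·MU/D, 1.5 s)` (dose rate D = 1000 MU/min by default; the robot
traversal time T_R = 1.5 s is taken as a direct configuration value since
the underlying path length is not specified); static segments cost 3.5 s
MLC positioning plus beam-on time, and a visited node with no MU costs only
the 1.5 s robot move. The first node of a dynamic trajectory is charged
like an interval — a choice the zero-MU micro-targets do not depend on.

## Synthetic world

The canonical fixture is a 300 × 300 × 200 mm unit-density water box with a
60 mm spherical PTV at its centre and the target point at the PTV centre.
The default voxel pitch is 2.5 mm; demonstration and acceptance runs use
5 mm to stay inside the grading time budget (stated where used). The fixed
arc trajectory is eight great-circle arcs of 13 nodes about horizontal axes
at azimuths k·22.5°, alternating tilt bands ±(2.5°–62.5°) from vertical —
104 nodes at exactly 5° spacing with all sources in the upper hemisphere.
The distribution of nodes among the arcs is not prescribed anywhere, so the
azimuth/tilt layout is this package's own; everything downstream depends
only on the node count, spacing, and hemisphere coverage. The body path is
a deterministic Fibonacci lattice of 110 sources within 75° of vertical, so
no beam enters through the couch. Two two-control-point demonstration
plans probe the motion model: complementary semicircular apertures (1000 +
1000 MU) whose static evaluation is uniform but whose delivered dose is
not, and mirrored 10 mm crescents (500 + 5500 MU) representing a
motion-aware plan whose delivered dose is uniform. The semicircle
orientation (which half each node covers) is a fixture flag, since either
choice is equally valid.

What a green test establishes: internal consistency of the dose models and
optimizer on a homogeneous phantom with idealized fluence physics. What it
does not: absolute dosimetry (no output factors, scatter kernels, or
heterogeneity corrections — the bixel-summation dose model is a known,
accepted simplification), robot kinematics or collision behaviour, and
clinical plan quality on patient anatomy.

## Numerical choices

* Influence truncation 1.5e-4 per column; sparse column storage per node.
* Phantom objective defaults: PTV `a = b = 1`, window [prescription,
  1.05 × prescription]; body `b = 0.1`, maximum at the prescription. The
  original per-case importance factors are not published, so these are
  package defaults, stated here once.
* Prescription renormalization: a single global MU scale sets PTV D95 equal
  to the prescription after DAO, mirroring how such plans are reported.
* DAO iterations default to 40, mirroring the fluence stage.
* Dyadic tie-breaks: longest above-level run per row, leftmost on ties;
  closed rows park at the mean centre of the open rows.
* The interdigitation rule closes the *narrower* of the two offending rows
  (the cheaper dose perturbation); which pair to close is not specified.
* Degenerate inputs: all-zero fluence maps sequence to an empty segment
  list; rays missing the phantom give empty influence columns; a V_pres of
  zero defines CI = 0.

## Known limitations

The DAO line search accepts zero steps when the projected direction fails
to descend, so convergence can stall before 40 iterations on
heavily-constrained problems; the objective is still monotone and all
acceptance quantities measure model consistency rather than plan
optimality. Delivery times ignore robot acceleration and trajectory
re-ordering of unused nodes. The step-and-shoot DAO shares the arc
machinery but does not re-allocate segments between nodes.
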