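---
title: "Methods: online dose assessment for prostate SABR setup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: online dose assessment for prostate SABR setup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sabrcheck)
```

## The problem

Prostate SABR delivers 8 Gy per fraction in five fractions, with dose
gradients of a few millimetres separating the prescription region from the
rectum and bladder. Day-to-day changes in organ filling therefore translate
directly into dose-constraint violations that a therapist looking at a
cone-beam CT (CBCT) must catch in the two to six minutes the patient is on
the couch. Visual decision-tree charts (estimate whether the bladder holds
two-thirds of its planning volume; scroll for anterior rectal distension)
are hard to apply consistently. `sabrcheck` replaces the visual step with
computed quantities: per-fraction DVH metrics for the daily organs at risk
(OARs), their classification against the clinical goal table, and the
decision-tree rules evaluated from measured volumes and distension counts.

## Dose superimposition

The package never recalculates dose. The planned distribution is treated as
a rigid "dose cloud": the dose at a daily point $p$ (CBCT frame) is the
planned dose sampled at $p + t$, where $t$ is the 3-DOF online
rigid-registration couch shift. This is the standard online approximation
for the pelvis — tissues near the prostate are nearly water-equivalent, and
VMAT delivery averages residual angular errors — and published comparisons
against full recalculation put its metric error at the few-percent level for
shifts up to about a centimetre. The two situations where the approximation
is known to degrade, large air cavities in the rectum and evaluation outside
the imaged volume, are handled by refusal and by accounting respectively:
the air-cavity shift scenarios are scope-guarded (requesting them raises an
error rather than producing an untestable number), and every dose sampling
reports the fraction of structure voxels that fell outside the dose grid
(out-of-grid voxels contribute 0 Gy).

Coordinates are DICOM patient coordinates in millimetres: +x patient-left,
+y patient-posterior, +z patient-superior, so *anterior is $-y$*. A couch
record of "isocenter shifted 4 mm anteriorly" is `rigid_shift(c(0, -4, 0))`.
A self-test on a posterior dose gradient pins this convention: an anterior
shift must lower the sampled dose when dose grows with $+y$.

Sampling is trilinear. The contract is exact reproduction of any affine
field (to $10^{-9}$) and of stored values at grid nodes; this is what makes
the shift-equivalence property (shifting sample points equals moving the
grid origin the other way) testable to machine precision.

## Contours to masks

Structures arrive as stacks of closed planar polygons (RTSTRUCT). A voxel
belongs to a structure iff its *centre* lies inside the union of that
slice's polygons under the even-odd rule, so coplanar nested contours carve
holes, and adding the same contour twice cancels (an involution the tests
check exhaustively on small grids). The crossing test uses a strict `<`
comparison, which resolves centres lying exactly on a vertical edge
deterministically; with integer-millimetre grids this makes a
$[0,10)\times[0,10)$ square rasterise to exactly 100 voxels. Contours are
assigned to the nearest grid slice and must lie within half a slice spacing
of one; anything farther is an error, because silently dropping or moving a
contour is how volume errors hide.

Volumes are voxel counts times voxel volume. At 1 mm spacing a
prostate-sized ellipsoid rasterises within 1% of $\frac{4}{3}\pi abc$; thin
tubes (a 12 mm-radius rectum) carry a lattice fluctuation of a few percent,
which is a property of counting lattice points in a narrow circle, not of
the rasteriser — the convergence test halves the spacing and watches the
error fall.

The "Rectum + 5 mm" planning structure is reproduced by Euclidean dilation
on voxel centres. The default is a true 3-D expansion, matching
treatment-planning-system margin tools; a slice-wise 2-D mode is available
because some clinics grow planning margins per slice, and the two differ at
the tube's superior/inferior ends. Whether the clinical structure was grown
in 2-D or 3-D is not documented, so the choice is a configuration, not a
constant.

## DVH metrics

Metrics are computed from the raw per-voxel doses, never from the binned
curve; the cumulative DVH exists for reporting and plotting only, so bin
width can never bias a classification. Conventions, each of which is a
documented choice with a test:

- $V_{x\,\mathrm{Gy}}$ counts voxels with dose $\ge x$ (closed inequality —
  conservative for OAR limits).
- $D_{v}$ interpolates the cumulative-volume curve linearly between voxel
  steps, so sub-voxel requests such as $D_{0.003\,\mathrm{cc}}$ are defined.
  A request below one voxel's volume returns the hottest voxel's dose with a
  *sub-resolution* warning: a point-dose metric probed below the dose-grid
  resolution is reported, not trusted. A request exceeding the structure
  volume by less than one voxel likewise returns the coldest voxel dose
  with a warning (the single-small-voxel edge); beyond that it is an error.
- Per-fraction doses are compared against the full-course limits without
  scaling. This is the deliberate worst-case reading used for online
  decisions: it assumes the dose pattern seen today repeats in every
  fraction.

A property worth stating because it drives clinical behaviour: for a fixed
absolute irradiated sub-volume, relative (percent-volume) metrics scale
exactly inversely with total organ volume — halving the bladder doubles
every percent metric while leaving absolute metrics untouched. The tests
assert this as exact floating-point doubling (the 1:2 volume ratio makes the
arithmetic commute with rounding).

## Goals and classification

The built-in goal table is the 40 Gy / 5-fraction prostate SABR protocol:
two tiers per goal, a preferred (primary) and, where defined, a mandatory
(secondary) limit. Meeting the primary is *optimal*; failing the primary but
meeting the secondary is a *minor* violation; failing the secondary is
*major*. Three structural decisions:

- A goal with no secondary limit is mandatory: failing it is major. The
  preferred/mandatory dichotomy leaves no minor tier for those rows. This is
  configurable per row.
- Comparisons are inclusive at the printed limit (a bladder
  $V_{37}$ of exactly 5 cm³ is optimal). Whether the clinic treated exact
  threshold values as pass is undocumented; inclusive was chosen and is
  configurable.
- The CTV coverage goal relaxes its *dose level* rather than its limit
  ($V_{40} \ge 95\%$ preferred, $V_{39.2} \ge 95\%$ mandatory), so the
  classifier accepts a separately computed secondary value. The femoral
  heads are carried as separate left/right rows (16 rows total), since each
  head is evaluated on its own structure.

Target (CTV/PTV) rows ship in the table but are excluded from the default
assessment profile: with intra-prostatic fiducial alignment, target coverage
is not the quantity the online decision hinges on. A flag enables them.

Aggregation is by worst class: per structure, and per fraction over all its
metrics. The classifier is monotone (for a $\le$ goal, increasing the value
never improves the class), which the suite checks by sweeping values.

## Decision rules

Only rules documented in prose are hard-coded; anything else belongs in the
rule configuration rather than being invented:

- **Bladder**: volume ratio $\ge 2/3$ of planning → B2 (proceed); below
  $2/3$ with no small-bowel increase inside the 80% isodose → B1N (proceed
  after the bowel-dose review); below $2/3$ with an increase → B1Y. The
  small-bowel check is an operator-supplied flag: small bowel is not
  auto-contoured and the CBCT field of view often excludes it. The B1Y
  action string ("task radiation oncologist for review") is inferred from
  the documented list of decision-tree actions and labelled as such.
- **Rectum**: anterior distension past the expanded planning rectum on at
  least three axial slices → flagged for review, with an anterior couch
  shift capped at 4 mm as the first remedy. Distension is measured per
  slice on the anterior extremum only (minimum $y$ of set voxels), because
  the rule is specifically about anterior distension; a full
  surface-distance analysis is out of scope.

The exact two-thirds boundary classifies as B2, with a $10^{-9}$ relative
tolerance absorbing the floating-point noise of percent conversions — a
volume measured to the microlitre should not flip a category.

`audit_concordance()` automates the retrospective chart audit: it
cross-tabulates the fired rules against the metric violation classes per
fraction and reports each rule's sensitivity for major violations.

## The gamma engine

Dose distributions are compared with a local-normalisation gamma index:
for each reference voxel $r$ above the low-dose threshold,

$$\gamma(r) = \min_{c}\,\sqrt{\frac{\lVert r-c\rVert^2}{\mathrm{DTA}^2} +
\frac{\left(D_e(c)-D_r(r)\right)^2}{\left(t\, D_r(r)\right)^2}},$$

with $t$ the local dose tolerance (default 2%), DTA the
distance-to-agreement (default 2 mm), and candidates $c$ on a regular
lattice of pitch DTA/interpolation-fraction (default 10, i.e. 0.2 mm)
inside a search ball, the evaluated dose trilinearly interpolated at each
candidate. Thresholding (default 10% of the reference maximum, with 50%
available to isolate the high-dose region) defines the evaluated set;
passing means $\gamma \le 1$.

Two implementations share this definition. `gamma_map()` visits candidates
in order of increasing distance and stops as soon as the pure distance term
exceeds the running minimum — valid because the dose term is non-negative —
which prunes most of the ball. `gamma_bruteforce()` evaluates the full
lattice with no pruning, in vectorised R rather than compiled code, and is
the oracle: the suite demands agreement within $10^{-9}$ across dozens of
random grid pairs. Closed forms pin the scale: self-comparison gives
$\gamma \equiv 0$; a spatially uniform 3% local offset under 2%/2 mm gives
$\gamma \equiv 1.5$ (no spatial candidate can reduce a pure dose error);
a steep linear gradient translated by exactly one DTA gives interior
$\gamma = 1$, provided the gradient is steep enough
($g/D \gtrsim 0.044\,\mathrm{mm}^{-1}$ at these parameters) that no closer
lattice candidate undercuts the exact match — a discreteness subtlety worth
knowing when constructing such fields.

The search ball radius defaults to $3\times$DTA. A candidate farther than
that can only win when its dose term is very small, and no cap at all would
make the search unbounded; the cap is configurable and the caveat
documented. Candidates outside the evaluated grid's support are skipped; a
voxel with no valid candidate reports $\gamma = \infty$.

## The synthetic phantom

Everything above is testable without clinical data because the phantom
module generates the inputs: an ellipsoidal bladder antero-superior to a
spherical target, a posterior rectal tube, and an analytic stand-in for the
planned dose — radially symmetric, prescription-level plateau with a
logistic falloff
$D(r) = \mathrm{Rx}/\left(1+e^{(r-r_0)/w}\right)$. The half-maximum sits
exactly at the plateau radius $r_0$ (a convenient closed form for tests)
and the centre dose equals the prescription to within the logistic tail,
below 0.1% for the defaults $r_0 = 25$ mm, $w = 3$ mm. No beam model is
attempted: the tool under test only superimposes and measures, so any
steep-gradient field exercises it, and $w$ is the dial that stresses the
high-dose metrics.

Inter-fraction change is emulated by three deterministic perturbations:

- **Bladder filling**: isotropic scaling to a target volume factor, about
  the centroid or about the target-side wall. Scaling moves contour planes
  off the slice lattice, so scaled stacks are re-sliced back onto regular
  planes by vertex-wise linear interpolation (phantom contours share vertex
  counts and angular parameterisation, which makes this exact for the
  shapes involved); without re-slicing, bunched near-coplanar contours
  would cancel under the even-odd rule. Rasterised volume ratios land
  within 0.5% of the requested factor.
- **Rectal filling**: in-plane radial scaling (volume scales with the
  square of the radius; the tube length is anatomy, not filling).
- **Anterior distension**: a bump of constant amplitude on a chosen number
  of slices, weighted around the circumference by anterior depth. The
  axial profile is a top-hat rather than a taper so that "amplitude 6 mm on
  5 slices" produces exactly five slices exceeding a 5 mm margin — the
  quantity the decision rule counts — instead of a profile-dependent
  subset.

The cohort sampler draws bladder volume ratios uniformly on
$[0.401, 1.857]$ and rectal ratios on $[0.570, 2.308]$ — the spans observed
across the 200-fraction clinical cohort this workflow was designed to audit
— for 40 patients × 5 fractions by default, with sub-centimetre couch
shifts (per-axis normal, SD 2 mm, clipped at ±8 mm) and distension events
on a quarter of fractions. The manifest alone reproduces every fraction
bit-for-bit.

Two designed studies sit on top:

- `distension_study()` sweeps bump amplitude 0–10 mm in a variant phantom
  (rectum 22 mm from the field centre, dose half-maximum at 28 mm with a
  2 mm falloff, 17 bumped slices) chosen so the sweep traverses all three
  violation classes of the rectum $V_{36}$ goal; the rule flags exactly the
  fractions with at least three distended slices, so its sensitivity for
  these engineered violations is 100%.
- `filling_study_spec()` places a smaller bladder with its target-side wall
  close to the field and is meant for target-side-anchored scaling: the
  absolute irradiated volume stays fixed while total volume changes, so
  relative-metric majors occur only in severely under-filled fractions
  (ratio < 2/3) — the volume law above, realised geometrically.

What passing these tests shows — and what it does not: the pipeline's
arithmetic, conventions, determinism and rule logic are verified end to
end, on anatomy that is smooth, convex, and noise-free. Real CBCT contours
carry auto-segmentation error, lattice-breaking shapes, partially imaged
organs and real registration residuals; none of those failure modes are
represented here, and clinical validation of the contour source remains a
prerequisite for clinical use of the numbers.

## File formats and their limits

The DICOM layer is a minimal, self-contained Part-10 codec: Explicit VR
Little Endian only, covering RTDOSE (16/32-bit, dose scaling mandatory,
uniform frame offsets mandatory, axial orientation only — anything else is
an error, never a silent resample), RTSTRUCT (CLOSED_PLANAR contours;
degenerate or non-planar contours are skipped with warnings; duplicate ROI
names are an error), and translation-only Spatial Registration objects
(a rotation block off identity by more than $10^{-4}$ is rejected: the
treatment couches are 3-DOF). Files written by the package re-read
bit-consistently (dose within half a scaling quantum, vertices within
$10^{-3}$ mm) and are cross-checked against an independent reader in the
test suite. Descending frame offsets are flipped so loaded geometry always
has strictly increasing $z$.

## Problem sizes and tolerances

Default working resolutions: 1 mm structure masks (1.25 mm in the cohort
and filling studies, where hundreds of fractions are assessed), 2.5 mm
analytic dose grids (the planning-system calculation resolution), 1.25 mm
for gamma comparison grids. Gamma oracle cross-checks run on grids of 5–8
voxels per side with a 3 mm search radius, plus spot checks at the default
6 mm radius; agreement is required to $10^{-9}$, exact-arithmetic contracts
(affine interpolation, translation equivariance) to $10^{-9}$–$10^{-12}$,
and voxelisation-dependent quantities to stated percentages (1% ellipsoid
volume, 2% volume-scaling, 10% for a 5 mm digital ball). JSON reports are
serialised at 17 significant digits so a written report reparses
bit-exactly.
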