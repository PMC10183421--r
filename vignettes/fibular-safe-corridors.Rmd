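---
title: "Geometry and statistics of fibular safe drilling corridors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and statistics of fibular safe drilling corridors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fibsafe)
```

## The problem

Syndesmotic injuries are commonly stabilized with a suture-button device
pulled through a drill tunnel that crosses the distal fibula and tibia.
Because the distal fibula is narrow, an eccentric tunnel can thin or breach
the anterior or posterior fibular cortex and predispose to
peri-implant fracture.  The question this package answers quantitatively
is: *from which segment of the lateral fibular cortex can a drill of a
given diameter reach a fixed medial tibial anchor without perforating the
anterior or posterior cortex?*  That segment is the **safe corridor**, and
it is computed for three device orientations: anteriorly angulated
(anteromedial tibial anchor), posteriorly angulated (posteromedial
anchor), and center-center.

All analysis is two dimensional, on an axial cross-section of the fibula
at the level where the device is placed, in physical millimetres.  The
canonical frame has +x pointing anterior and +y lateral; left-sided data
are mirrored about the y axis at ingest so that a single right-side frame
is analysed throughout.

## The geometric model

A subject is a `cross_section`: a simple, counter-clockwise closed
fibular contour, plus five landmarks — the anterior (7), posterior (8)
and lateral (9) cortical apexes on the contour, and the two tibial anchor
points (1, anteromedial; 4, posteromedial) outside and medial to it.
Two derived points complete the scheme: the tibial centre (10, anchor
midpoint) and the fibular centre (11, midpoint of the 7–8 apex chord).

**Signed locations.**  The lateral cortex is split at the lateral apex
into the anterolateral path (9 to 7) and the posterolateral path (9 to 8).
A point on either path is reported as a signed percentage of that path's
arc length: 0 at the lateral apex, +100 at the anterior apex, −100 at the
posterior apex.  Arc length (not the straight 9–7 / 9–8 chord) is used;
the chord variant is available via `aspect_ratio(chord = TRUE)` for
comparison.  Because the measure is a ratio of arc lengths it is
invariant under any similarity transform of the section — the property
that allows per-subject percentages to be pooled across a cohort without
registration.

**The drill as a strip.**  The tunnel axis is a line through the fixed
medial anchor; rotation about the anchor is the single degree of freedom.
A finite drill of diameter $d$ is modelled as the strip of width $d$
centred on the axis.  A configuration is *feasible* when both strip
boundary lines still intersect the bone contour — i.e. the hole does not
break out through the anterior or posterior cortex — and the axis itself
exits through the lateral cortex.  When the axis crosses the lateral
cortex more than once (possible for irregular sections) the exit is the
crossing farthest from the anchor: the drill exits the far cortex.

**Extreme tunnels.**  For each angulated orientation the most anteriorly
and posteriorly rotated feasible axes define the subject's feasible exit
interval.  On convex sections the extremes are solved analytically: at an
extreme rotation a strip boundary is tangent to the contour at a vertex
$v$, so candidate angles are
$\mathrm{atan2}(v - a) \pm \arcsin\!\big(d / (2\,\lVert v - a\rVert)\big)$
over all vertices $v$ (plus the axis-through-vertex angles, where the
binding constraint switches from tangency to the lateral-exit condition);
the extremes are the outermost feasible candidates.  Non-convex sections
fall back to an angular sweep (0.2° grid over the anchor's angular window)
with bisection refinement of the feasibility boundary to $10^{-4}$°.  The
two solvers agree to well below 0.05° on convex sections, which the test
suite verifies against an independent raster-containment oracle.

A geometric subtlety worth stating: the zero-diameter extremes pass
exactly through apexes 7 and 8 (borders exactly ±100%) *when the anchor
lies in the medial wedge from which both apexes are silhouette vertices
of the contour*.  The anatomical anchors are more oblique than that: the
anteromedial anchor sits beyond the support line of the anterior cortex,
the axis runs nearly parallel to that cortex, and the whole feasible
interval collapses onto the posterior side of the lateral apex (and
mirrored for the posteromedial anchor).  That obliquity — not the strip
width — is what makes the anteriorly angulated corridor live entirely in
negative (posterior) territory.

**Ideal and center-center axes.**  The ideal angulated tunnel runs from
the anchor through point M, the bisector of the fibular width, taken as
the midpoint of the 7–8 apex chord (a chord-midpoint alternative,
iterating the midpoint of the bone chord cut by the axis, is exposed via
`m_definition = "chord_midpoint"` since "bisector of the width" is
ambiguous).  The center-center orientation is the single axis through
points 10 and 11; it has no angular freedom, so no borders are defined
for it.

## Registration

Every subject's apex triple (7, 8, 9) is superimposed onto a reference by
Procrustes analysis: the similarity transform (rotation, uniform scale,
translation) minimising the sum of squared landmark distances, in closed
form via complex least squares.  Reflection is excluded because side
canonicalization already happens at ingest.  Scaling is included by
default — pooling percent-based results across subjects is size-free, so
the overlay should be too — and a rigid variant is available
(`allow_scale = FALSE`).  The registration quality metric is the mean
distance of the transformed apexes from the reference apexes (mm).

The default reference policy iterates the generalized-Procrustes mean
shape to convergence (coordinate change below $10^{-8}$); a fixed
reference subject (`"first"` or a subject id) reproduces the
single-reference-image design.  Registration is used for overlay and QC
only: corridor statistics consume the raw per-subject percentages, which
are similarity invariants, and a pipeline test asserts that corridor
numbers are unchanged whether tunnels are solved before or after
registration.

## Cohort statistics

Per-subject feasible intervals are aggregated per orientation:

* **Angulated corridors** are the *intersection* of the per-subject
  intervals — the minimum of the anterior borders and the maximum of the
  posterior borders.  An empty intersection is representable and flagged,
  not an error.  A cohort-range alternative (`mode = "range"`) is exposed
  for comparison.  Infeasible subjects are excluded and counted.
* The **central corridor** is the min–max range of the per-subject
  center-center locations.
* Descriptives follow the mean ± sd (range) convention with the $n-1$
  sample sd; paired comparisons use the paired t-test and Pearson
  correlation (`paired_t_and_pearson()`), with degenerate inputs flagged
  rather than fatal.

## The synthetic cohort generator

No imaging data ship with the package, so `generate_cohort()` produces
cross-sections with the statistical structure the analysis assumes:

* **Shape mixture** 81% triangular convex, 8% quadrilateral, 10%
  irregular; the truly triangular class receives the residual 1% (the
  published mixture sums to 99% without naming it).
* **Lateral aspect ratio** (anterolateral / posterolateral edge length)
  follows a truncated normal on [0.7, 1.5] *calibrated so that the
  realized mean and sd equal 1.0 and 0.2*.  Naive truncation of a
  N(1.0, 0.2²) law would give mean 1.024 and sd 0.169; the underlying
  location and scale are therefore solved (mu ≈ 0.80, s ≈ 0.36) so the
  generated cohort reproduces the statistics it is meant to emulate.
* **Scale**: apex chord ~25 ± 2 mm, lateral depth ~15 ± 1.5 mm — plausible
  magnitudes for the distal fibula, config-exposed, with no claim of
  anatomical authority.
* **Classes**: the triangular classes place the lateral apex on the
  Apollonius locus realising the drawn edge ratio exactly; the convex
  variant replaces the medial edge by a circular arc of sagitta 0.15 ×
  chord.  The quadrilateral adds a fourth corner as an outward kink
  (offset 0.20–0.30 of the posterior face chord) so all four corners stay
  above the 35° corner-detection threshold.  The irregular class
  modulates a corner-smoothed triangular radial template (60° circular
  smoothing window) with low-frequency Fourier harmonics (k = 2, 3,
  relative amplitudes 0.02–0.07); smoothing is essential — an unsmoothed
  perturbed triangle keeps three dominant corners and would correctly be
  classified as triangular, so the class would be unrealizable.  The
  construction is star-shaped, hence always simple.
* **Anchors** sit at configurable offsets from the apex-chord midpoint,
  by default (+26, −15) mm anteromedially and (−22, −16) mm
  posteromedially with 2 mm per-subject jitter — oblique placements that
  reproduce the published sign structure of the corridors.
* **Noise** is isotropic Gaussian jitter (sd 0.3 mm) on the landmark
  *annotations* only, emulating manual marking; jittered apexes are
  projected back onto the contour, as a human annotator clicks on the
  visible cortex.  Contours themselves are noise-free.
* **Heights**: simulated slice heights (19 ± 3 mm above the plafond,
  44 ± 4 mm above the fibular tip) are generated with Pearson correlation
  0.42 to a patient-height covariate (172 ± 9 cm); operated-side heights
  add a 4 ± 5 mm shift, giving the paired-comparison structure.
  54% of subjects are left-sided and mirrored through the file round trip.

What passing tests on this cohort do **not** show: anatomical realism of
real fibulae (cortical thickness, incisura congruence, 3-D obliquity of
the drill relative to the axial plane), CT segmentation error, or
observer variability beyond isotropic landmark jitter.  Corridor
magnitudes on synthetic cohorts are therefore structural results (sign
pattern, ordering, interval logic), not clinical values.

## Numerical choices

* Geometric tolerance for intersection/tangency tests: $10^{-9}$ mm,
  surfaced as `eps` everywhere.
* Landmark snap tolerance onto the contour: 0.1 mm (in-plane CT
  resolution scale); apexes are projected to the nearest contour point.
* Corner rule for classification: turning angle above 35° integrated
  over a 2 mm arc window; medial-edge straightness below 4% of the chord;
  convexity requires all medial deviations on the medial side with
  consistent turning sign (≥ 90%).  The published classification was
  visual; these thresholds are a declared operationalization,
  config-exposed, not the original authors' procedure.
* Sweep solver: 0.2° coarse grid, bisection to $10^{-4}$°; ties in the
  border labelling are resolved by the signed exit value (anterior border
  = larger value).
* Degenerate inputs: `strip_within_fibula()` returns `FALSE` rather than
  erroring; per-orientation solver failures are carried as
  `feasible = FALSE` without aborting other orientations; the pipeline
  aborts only when every subject fails.

## Problem sizes used by the tests

The test suite exercises the solvers at the sizes a single CPU handles
comfortably: 200 convex sections for the analytic-vs-raster sweep
comparison, a 100-subject cohort for the diameter monotonicity law, a
200-subject noiseless cohort for parameter recovery, 96 subjects (the
published cohort size) for the sign-structure check, and 1000 draws for
the generator's distributional laws.  `scripts/acceptance.R` regenerates
a 96-subject default cohort and recomputes every reported quantity from
scratch.

## Known limitations

* The strip model checks the fibular cortex only; tibial passage,
  neurovascular structures and implant mechanics are out of scope.
* Corridors are intersections over subjects: one extreme subject can
  narrow (or empty) the cohort corridor — the range mode is provided to
  inspect that sensitivity.
* The analytic solver requires convexity; irregular sections use the
  sweep, whose extreme angles are exact only to the bisection tolerance.
* With three landmarks the Procrustes fit is exact for similar triangles;
  the mean distance error therefore measures shape heterogeneity plus
  annotation noise, and cohorts of similar shapes register with zero
  error regardless of the reference policy.

## A worked run

```{r, eval = FALSE}
cohort <- generate_cohort(cohort_params(n_subjects = 96, seed = 1))
shapes <- shape_metrics(cohort)
solutions <- simulate_tunnels(cohort)
registration <- register_cohort(cohort)
report <- corridor_report(solutions)
report
autoplot(report)
plot_overlay(registration, solutions)
```

Or in one step, writing all artifact files:

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(
  cohort = cohort_params(n_subjects = 96),
  seed = 1, out_dir = "corridor_run"
))
```
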