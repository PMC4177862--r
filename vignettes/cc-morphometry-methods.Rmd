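---
title: "Corpus callosum morphometry: models, parameters and design choices"
author: "ccmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corpus callosum morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

ccmorph implements a morphometric comparison of the corpus callosum (CC) on
the midsagittal plane between a congenitally blind (CB) and a sighted
control (NC) cohort. Four stages make up the analysis:

1. **Shape.** For each subject's binary CC mask, the minimum rectangle
   covering the region of interest is constructed, and the *bending angle*
   is the vertex angle of the isosceles triangle sharing the rectangle's
   base $b$ and height $h$:
   $$\theta = 2\arctan\!\frac{b}{2h}.$$
   A taller arch (larger $h$ at fixed $b$) gives a smaller, "more convex"
   angle. $\theta$ is scale-invariant and strictly monotone in $b$ and $h$,
   and both properties are asserted by tests.
2. **Subdivision.** Four cuts perpendicular to the rectangle's long side
   split the CC into five contiguous sub-regions covering 33, 17, 17, 13
   and 20 % of its length, ordered rostro-caudally: anterior third (rostrum
   + genu + rostral body, deliberately kept as one region), anterior
   mid-body, posterior mid-body, isthmus, splenium.
3. **Template and areas.** An unbiased group-average template is built by
   iterative nonlinear registration; sub-regional areas per subject are the
   integrals of the Jacobian determinant of the template-to-subject
   deformation field over the template-space labels. This measures every
   subject's areas through one common labelling, so group differences in
   CC *shape* cannot masquerade as area differences.
4. **Statistics.** Per region, an ANCOVA of area on group (and sex) with
   age as covariate, Type III sums of squares under sum-to-zero coding;
   Bonferroni gating across the five regions at the fixed inclusive
   threshold $p \le 0.01$; Scheffé post-hoc contrasts among the four
   group-by-sex cells where the interaction is significant; and a one-way
   site ANOVA on native-space whole-CC area as an acquisition check.

# Conventions that had to be fixed

Several details are under-determined by the procedure sketched above; each
was decided once and is recorded here.

**Pixel extent vs pixel center.** Rectangle lengths default to the
`pixel_extent` convention (bounds of pixel *boundaries*: a filled run of
$n$ pixels at 1 mm spans $n$ mm), because areas elsewhere count whole
pixels and the two measures should agree. The `pixel_center` convention is
selectable.

**Axis-aligned vs rotated rectangle.** Masks are assumed AC-PC aligned, so
the default rectangle is axis-aligned. A true minimum-area rotated
rectangle (rotating calipers over the convex hull) is provided as
`min_area` and is verified against an exhaustive 0.1° rotation search; the
pipeline records which mode produced its numbers.

**Slab membership.** A pixel belongs to the slab whose half-open interval
$[s_k, e_k)$ along the base axis contains its center; the last slab is
closed. Cuts sit at cumulative fractions 0.33, 0.50, 0.67, 0.80 of the
base length from the anterior end. The image handedness is never guessed:
`anteriorDirection` (`"+col"` or `"-col"`) must be declared.

**Anatomical orientation.** Because the on-disk orientation of a
midsagittal slice is site-dependent, NIfTI images are reoriented to a
canonical axis order on reading, and everything downstream depends only on
the declared anterior direction.

# Registration

The template-building algorithm is a 2-D demons-style matcher: at each
iteration the sum-of-squared-differences force
$v = -\,\delta\,\nabla I / (|\nabla I|^2 + \delta^2)$ (with $\delta$ the
intensity difference) is added to the displacement field, which is then
smoothed with a Gaussian — the discrete analogue of diffusion
regularisation. Matching runs coarse-to-fine over a schedule of
regularisation scales (default 16, 8, 4, 2 px; field smoothing
$\sigma = \text{scale}/2$), with a per-iteration step cap of 2 px and at
most 150 iterations per scale (the cap is reported via a `converged` flag
and a warning when hit; in practice only the finest scale hits it, where
residual boundary jitter is sub-tolerance in area terms).

Binary masks are Gaussian-smoothed ($\sigma = 0.8$ px) into soft-edged
images before matching, because binary SSD has flat gradients; 0.8 px is
the largest smoothing for which thresholding the smoothed mask at 0.5
reproduces the original mask with Dice > 0.99, keeping the template mask
faithful to the cohort.

Fields are stored **template → subject**, so integrating $\det(I+\nabla u)$
over a template-space label directly yields that subject's area; the
convention is asserted by tests (a subject 10 % larger than the template
must yield $\det J \approx 1.21$). Non-positive determinants are counted
and reported, never clamped — clamping would silently bias areas.

Template construction follows the unbiased iterative scheme: register all
subjects to the current template, resample, average, then warp the average
by the *inverse of the mean deformation*, which removes net bias (after
the final pass the voxelwise mean displacement is below 0.2 px on
two-subject constructions, per test). Iteration $i$ uses only the first
$i$ entries of the scale schedule, so early iterations capture gross
differences and later ones refine. Registration is fully deterministic;
stochastic initialisation is excluded by contract. The number of template
iterations and the grid schedule are this package's own defaults (4
iterations, 16/8/4/2 px), stated rather than inherited: no reference
values exist for them.

The whole-brain linear normalisation that precedes template building in an
MRI study is abstracted to a scalar per-subject `linear_scale`; native
areas are stereotaxic areas divided by its square. The generator sets it
to 1 by default, making the two spaces coincide — a deliberate, flagged
simplification.

# The synthetic cohort generator

Real MRI data are not distributed with the package, so validation rests on
synthetic cohorts with *known ground truth*. `makeCCShape()` draws an arch:
a half-ellipse centerline spanning the base, thickened per slab
(piecewise-constant thickness with short cosine tapers at slab joins,
renormalised per slab so the planted areas are exact in the continuum).
The apex and foot of the arch are solved so the bounding rectangle
reproduces the requested base and height to within half a pixel per axis,
making the planted bending angle recoverable to about a degree at 1 mm
pixels (the residual is pure quantisation; the recovery test therefore
runs at 0.5 mm). Rasterisation uses per-column error diffusion, reset at
slab boundaries, so pixel-counted slab areas track the planted areas to
sub-pixel error; a bridging pass keeps the shape 4-connected where the
arch shoulders are steeper than the band is thick.

`sampleMaskCohort()` draws per-subject region areas and a bending angle
from the group distributions — normal, truncated at 3 SD (a deliberate
deviation from a pure normal model that keeps geometry feasible), with
joint redraws when an area/angle combination is infeasible — and converts
the angle to rectangle geometry by inverting the bending formula.
`simulateAreaTable()` draws *untruncated* normals (its law-of-large-numbers
contract checks mean and SD to 0.2 mm²) and bypasses imaging entirely.

The default cohort (in `inst/extdata/cb_cohort.yaml`) encodes the study
conditions: 28 subjects per group, 16 male / 12 female, CB angles
109.6 ± 4.9° vs NC 113.4 ± 5.7°, splenium 225.64 ± 31.7 vs
260.84 ± 41.7 mm², posterior mid-body 107.26 ± 21.67 vs 89.64 ± 16.51 mm²,
isthmus 79.4 ± 16.66 vs 64.16 ± 10.31 mm² with the four isthmus
group-by-sex cells listed separately. The anterior third
(300 ± 40 mm²) and anterior mid-body (100 ± 15 mm²) carry no group
difference and are realistic adult magnitudes chosen once; the base length
(100 ± 3 mm) is chosen so the group-mean angles correspond to heights of
35.27 and 32.84 mm, the rectangles used as closed-form checkpoints.

What the generator does **not** emulate: anatomically realistic CC
contours (rostrum hook, splenium bulb), segmentation noise, partial-volume
effects, or any raw-intensity phenomena. Passing tests therefore show that
the measurement chain recovers known geometry and statistics, not that it
is robust to manual-segmentation variability.

# Statistics: model conventions

Type III sums of squares with sum-to-zero factor coding are used because
interaction and main effects are reported side by side, and it is the only
convention under which the four isthmus cell means and SDs reproduce the
reported interaction F of about 7.2 at the printed sample sizes. Age
enters linearly and uncentred (centring provably leaves every F unchanged;
a test asserts it). The Bonferroni gate applies the literal inclusive
threshold $p \le 0.01$ rather than recomputing $0.05/5$ with strict
inequality. Scheffé p values use
$P\{F_{k-1,\nu} > F_\text{contrast}/(k-1)\}$ with $k = 4$ cells, valid
simultaneously for all linear contrasts and hence conservative for
pairwise ones (asserted against unadjusted p values). Welch-type
corrections are deliberately absent: the analysis is classical ANCOVA.

Denominator degrees of freedom follow this package's own model arithmetic:
a one-factor-plus-age model on 56 subjects has 53 denominator df, the
two-factor interaction model 51. Published per-region F statistics of this
design are sometimes quoted with 54 and 52; the discrepancy (one df) is
documented rather than forced.

One statistical subtlety is worth recording. When cohorts are simulated
*from* reported cell means and SDs, the **mean** simulated F statistic
exceeds the plug-in F computed at those same parameters by a factor of
approximately $(1 + \mathrm{Var}(\hat L)/L^2)\,\nu/(\nu-2)$ (noise in the
contrast estimate plus the expectation of the reciprocal MSE). For strong
effects (group F near 12) the inflation is ~8–12 %; for the weaker isthmus
interaction (F near 7.2) it is ~17 %, so the replicate-averaged interaction
F sits near 8.5, not 7.2 — the median, by contrast, is close to 7. The
package reports the mean as specified for its recovery checks and leaves
this inflation visible rather than re-tuning inputs.

# Problem sizes and numerical tolerances

The validation suite runs entirely on synthetic data at desk scale, chosen
as the smallest sizes at which each property is meaningfully testable:
registration oracles on ~80 × 28 mm arches in 60 × 110 px canvases;
template parameter recovery on a 12-subject cohort (6 per group) at a
coarse 8/4/2 px schedule, where planted splenium areas are recovered
within 5 % per subject and whole-CC Jacobian-integrated area agrees with
the subject's own pixel count within 5 % (typically 0.5 %); F-statistic
recovery and type-I calibration on 2000 replicates of the full 28 + 28
design; the law-of-large-numbers check on 10⁶ area draws. Narrow slabs
carry the largest relative boundary-placement error in template space (a
one-pixel shift is ~8 % of the isthmus), which is why per-region
area-agreement contracts are stated for the splenium and the whole CC.

Numerical choices: binarisation threshold 0.5 on normalised intensity;
template threshold 0.5; min-area rectangle ties broken toward the first
hull edge attaining the minimum; slab cuts use exact cumulative fractions
with the half-open rule so counts are bit-reproducible; all cohort
generation flows from one master seed fanned out deterministically per
subject, so any subject can be regenerated in isolation.

# Known limitations

* The arch generator controls the bounding rectangle and slab areas
  exactly but is not anatomically realistic; effect sizes planted in it
  transfer to real data only to the extent that registration quality
  transfers.
* Jacobian-integrated areas for the narrowest slab (isthmus, 13 % of the
  base) are sensitive to one-pixel boundary placement on the template at
  1 mm resolution.
* The demons matcher is intensity-based on soft masks; it has no landmark
  or curvature terms and will not recover large rotations (masks are
  assumed AC-PC aligned upstream).
* The scalar `linear_scale` stands in for a full affine normalisation;
  anisotropic brain scaling is out of scope.
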