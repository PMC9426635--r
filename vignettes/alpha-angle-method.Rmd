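---
title: "Measuring the alpha angle from landmark outlines: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the alpha angle from landmark outlines: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphangle)
```

## The measurement problem

Cam morphology — an aspherical bulge of the lateral femoral head — is
quantified by the alpha angle (AA): the angle at the centre of the
femoral-head circle of best fit between the ray towards the femoral-neck
midpoint and the ray towards the point where the bone outline leaves the
circle. Manual measurement is slow and rater-dependent; when outlines are
available as ordered landmark coordinates the whole construction can be
automated. This package implements that automation for the standard
85-point proximal-femur scheme, of which landmarks 8–39 (medial neck,
head, lateral neck) are consumed.

All geometry is computed in millimetres: coordinates are multiplied by
`pixel_spacing_mm` on the way in, because the decision threshold at the
heart of the method (below) is an absolute 1 mm. All geometry also assumes
a left hip; right-hip outlines are mirrored about the vertical image
midline first (`mirror_points()`), which preserves the landmark order and
flips only the x coordinate.

## Pipeline and the four decision rules

`compute_alpha()` runs, in order:

1. **Circle fit** (`fit_circle()`): algebraic (Kåsa) least squares on
   landmarks 15–28. The algebraic fit solves a 3×3 linear system; for
   near-circular landmark sets it agrees with the iterative geometric fit
   to far below the millimetre scale that matters here (the test suite
   cross-checks against a Nelder–Mead geometric fit). The fit stops at
   landmark 28 rather than 30 deliberately: the two landmarks nearest the
   superior-lateral curvature are the ones a cam deforms most, and
   including them would drag the circle outward and mask the very bulge
   being measured.
2. **Residuals** (`compute_residuals()`): signed distance to the circle,
   positive outside, for landmarks 15–39.
3. **Neck search** (`neck_narrowest()`): consecutive-landmark segments on
   each side of the neck (8–12 medial, 32–36 lateral) are tested against
   every landmark of the opposing side, in both directions, using
   *clamped* point-to-segment distance. The clamp matters: neck landmark
   runs are short, and the perpendicular foot of an opposing point often
   falls beyond a segment's end; measuring to the infinite line would
   under-estimate the width there. Widths are compared exactly (no
   epsilon) and the first minimal pair in landmark order wins ties.
4. **Index-point threshold** (`index_point_threshold()`): the residual a
   candidate must exceed. Under models 1–2 it is the maximum *signed*
   residual over the fit landmarks (floored at zero). Models 3–4 take the
   maximum *absolute* residual — a head that bulges inward of the circle
   is also poorly fitted — and floor it at 1 mm, an approximation of what
   is discernible by eye on the image. The floor suppresses index points
   on near-perfect spherical heads where a landmark sits a fraction of a
   millimetre outside an excellent fit.
5. **Index-point scan** (`find_index_point()`): candidates are landmarks
   29–37 in increasing order (so that two successors always exist within
   the used range of 39; the upper bound is a package choice, since only
   "after 28" is anatomically fixed). With residual `r` and threshold `T`:
   model 1 takes the first `c` with `r(c) > T` and `r(c+1) > r(c)`;
   models 2–3 require the strictly increasing run `r(c) < r(c+1) <
   r(c+2)` above `T`; model 4 keeps the three-point run but drops the
   increase: `r(c), r(c+1), r(c+2) > T`. The progression mirrors how such
   rules evolve in practice: rule 1 is too eager (noise wobbles outside a
   tight fit trigger it), the increasing-run rule over-corrects
   (plateauing bulges are missed), and the final rule balances the two.
   Residual comparisons are exact floating point — a bump whose largest
   residual is 0.96 mm genuinely misses a 1 mm floor, and the suite pins
   that behaviour.
6. **Intersection position** (`intersection_position()`): when the
   landmark before the index point lies inside the circle the outline
   demonstrably crosses it, and the exact segment–circle intersection is
   used (`EXACT_CROSSING`; the returned point is on the circle to 1e-9·r,
   and tangency — discriminant below 1e-12·r² — counts as no crossing).
   Otherwise the position is approximated by a landmark: models 1–2 take
   the landmark before the index point; models 3–4 take whichever of
   {before, index, after} has the smallest absolute residual, i.e. the
   best stand-in for the missing crossing.
7. **Angle and classification**: the arccosine of the normalised dot
   product of the two rays, in [0°, 180°]; cam morphology is
   `AA >= cam_threshold_deg` (default 60; 50, 55 and 83 are also found in
   the literature, hence the argument).

When no candidate satisfies the rule the result is `NO_DEVIATION` rather
than an invented angle: the outline, at the sampled resolution, never
measurably leaves the circle. Downstream code (CSV export, the agreement
battery) treats such angles as missing. This explicit status is a design
choice — the alternative of reporting 0° would poison means and
agreement statistics.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `model_version` | 4 | – | the final, most robust decision rule |
| `pixel_spacing_mm` | 1 | mm/unit | coordinates already in mm; override per scanner |
| `min_threshold_mm` | 1 | mm | visibility floor of models 3–4 |
| `cam_threshold_deg` | 60 | degrees | conventional cam cut-off |
| candidates | 29–37 | landmark | "first point after 28", bounded so successors exist |

## What the synthetic generator emulates — and what it does not

`generate_outline()` builds a parametric left hip: a circular head of
radius `head_radius` (default 25 mm, a typical adult femoral head),
landmarks 15–30 equally spaced over the head arc from the inferior-medial
(55° from the neck axis) to the superior-lateral curvature (63°), short
transition landmarks, and neck landmarks flanking a narrowest region of
width `neck_width`. The neck is symmetric about its axis, so the
neck-midpoint ray points along the axis; consequently the angular position
of any feature on the head *is* its alpha angle, which is what makes
ground truth exact by construction.

A cam is a radial bulge added to the lateral side: zero (with zero slope)
at `cam_onset_deg`, rising along a raised-cosine ramp over
`cam_extent_deg` (default 40°) to `cam_amplitude`, and staying at full
amplitude through the head–neck junction, as a real cam lesion does. The
onset angle is therefore the ground-truth AA whenever the amplitude
exceeds the 1 mm detection floor. A strictly local bump (zero on both
sides) was considered and rejected: the index scan starts at landmark 29,
and a bulge confined to high head angles leaves nothing for the scan to
detect, making the stated ground truth meaningless.

Two idealisations matter when interpreting test results:

* **The sampled neck is a short stub held just inside the head circle**
  (radial deficits ≤ 0.6 mm). On real anatomy the distal neck leaves the
  head circle and every hip eventually "deviates" at the junction, giving
  a baseline junction-angle AA even for spherical heads. The generator
  deliberately avoids this so that a pristine no-cam outline yields
  `NO_DEVIATION` — a clean negative control. Passing tests therefore
  demonstrate correct rule behaviour, not that real no-cam hips return
  `NO_DEVIATION` (they generally will not).
* **Angular quantisation.** Landmarks sample the head arc every
  `landmark_spacing_deg()` ≈ 16°; the measured AA snaps to landmark
  positions (or exact crossings between them). Recovery of a continuous
  onset angle is accordingly assessed against a tolerance of one
  inter-landmark spacing, and measured AA is a step function of onset —
  non-decreasing up to sub-degree wobble caused by the bump slightly
  shifting the neck midpoint. Onsets above the angular position of
  landmark 28 (≈ 95° with the default layout) are attributed to that
  landmark's angle, so tracking was verified over onsets 40°–110° but
  cannot extend far beyond.

`generate_cohort()` draws head radius (23–27 mm), neck proportions
(width ≈ 0.8 × radius), axis direction (190°–230° in image coordinates),
onset (40°–100°) and amplitude (2–6 mm) per hip, with 0.2 mm landmark
noise by default — of the order of the manual corrections applied to
automatically placed points on real images. Gaussian landmark noise is an
approximation; real placement errors are correlated along the boundary
and occasionally gross (mis-placed points), which the generator does not
emulate — hence the batch interface records per-image failures as data
instead of assuming they cannot happen.

## Validation harness

The test suite (and `scripts/acceptance.R`) validates three layers, at
problem sizes chosen to run in seconds: geometric primitives against
independent oracles (closed-form circumcircle, a geometric circle fit,
dense-sampling brute force for the neck search, on-circle checks for
crossings); the decision rules against a hand-traced battery of
constructed residual profiles for all four models; and the full pipeline
against generator ground truth on a 200-hip cohort (recovery error,
cam sensitivity/specificity away from the 60° boundary) plus a
simulated manual rater (truth + 3° noise) pushed through the same
agreement battery — Lin's CCC with a Fisher-z interval using Lin's
asymptotic variance (the construction common statistical software
defaults to; the package reports population-moment CCC per the original
estimator), binary Cohen kappa with percentage agreement, mean absolute
difference, and Bland–Altman limits with outlier flagging, dropping
incomplete pairs listwise with a logged count.

## Known limitations

* AA resolution is bounded by landmark density (~16° on the default
  layout); sub-spacing onset differences are not distinguishable.
* The method measures where the outline leaves the circle *scanning
  laterally from landmark 29*; pathologies expressed only at more
  superior angles surface indirectly (through fit distortion), not as a
  directly located intersection.
* `NO_DEVIATION` is a property of the outline at its sampled resolution,
  not proof of sphericity.
* The agreement module implements binary kappa only; weighted or
  multi-category kappa and intraclass correlation variants are out of
  scope.
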