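# alphangle

Automated measurement of the **alpha angle (AA)** of the hip from ordered
landmark outlines of the proximal femur on anterior-posterior images, with
**cam morphology** classification (AA ≥ 60°), the inter-rater agreement
statistics used to validate such a measure, and a synthetic-hip generator
with known ground truth so the whole pipeline can be exercised without
access to clinical imaging data.

The package is aimed at musculoskeletal imaging researchers who have
landmark point files (e.g. from DXA shape-annotation pipelines) and want a
reproducible, scriptable AA measurement instead of manual goniometry.

## The measurement

The alpha angle is defined from three geometric features of the outline:

1. **Circle of best fit.** A circle is fitted by least squares to the
   femoral-head landmarks 15–28 (stopping two landmarks short of the
   superior-lateral curvature so a cam bulge does not drag the fit). With
   centre *c* and radius *r*, each landmark *p* has a signed residual
   `d(p) = ‖p − c‖ − r` (positive outside the circle).
2. **Femoral neck midpoint.** The neck is demarcated medially by landmarks
   8–12 and laterally by 32–36. For every segment joining consecutive
   landmarks on one side, the shortest (clamped) distance to each landmark
   on the other side is measured in both directions; the global minimum is
   the narrowest neck width and the midpoint of that line is the neck
   point *m*.
3. **Index point and intersection position.** Scanning landmarks 29, 30, …
   the *index point* is the first landmark judged truly outside the
   circle. Four decision rules of increasing robustness are provided
   (`model_version` 1–4). The final rule (model 4) requires the residuals
   of the candidate and its two successors to all exceed a per-image
   threshold `T = max(1 mm, max |d| over landmarks 15–28)`. Where the
   outline crosses the circle between the index point and its predecessor
   the exact crossing *x* is used; otherwise *x* is approximated by the
   neighbouring landmark closest to the circle.

Then

```
AA = arccos( (m − c)·(x − c) / (‖m − c‖ ‖x − c‖) )
```

in degrees, and cam morphology is called when AA ≥ 60°.

Agreement between two sets of measurements (e.g. automatic vs manual) is
summarised by Lin's concordance correlation coefficient
`ρ_c = 2 cov(x,y) / (σ²x + σ²y + (μx − μy)²)` with a Fisher-z confidence
interval, Cohen's kappa on the cam classification with percentage
agreement, the mean absolute difference with its SD, and Bland–Altman
limits of agreement `mean(d) ± 1.96 sd(d)` with outlier identification.

## Worked example

```r
library(alphangle)

spec <- synthetic_hip_spec(cam_onset_deg = 80, cam_amplitude = 4,
                           noise_sd = 0.2, seed = 7)
hip <- generate_outline(spec)   # landmarks 8-39, ground truth AA = 80
res <- compute_alpha(hip$points)
res
#> <alpha_result> "synthetic": alpha 72.3 deg (model 4), cam: yes
res$circle
#> <circle_fit> centre (90.057, 79.972) mm, radius 24.999 mm, rms 0.1862 mm
res$neck
#> <neck_measurement> width 21.732 mm, midpoint (69.685, 67.268) mm
res$index
#> <index_point> FOUND (threshold 1.000 mm, model 4), landmark 30
```

The generating head circle (centre (90, 80), radius 25 mm) is recovered to
within the 0.2 mm landmark noise, and the measured 72.3° sits one
landmark's angular spacing below the true 80° onset — landmark outlines
sample the head arc about every 16°, which is the resolution limit of any
landmark-based AA. `glance(res)` returns the same record as a one-row
tibble; `tidy(res)` gives the per-landmark residual profile, and
`autoplot(res)` draws the outline, fitted circle, neck line and the two
rays of the angle.

Batch use from a shell (after installing, see `exec/alphangle`):

```sh
alphangle simulate --n 100 --output pts/ --cam-fraction 0.33 --seed 1
alphangle compute  --input pts/ --output auto.csv --model 4
alphangle compare  --auto auto.csv --manual manual.csv --report stats.json
```

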