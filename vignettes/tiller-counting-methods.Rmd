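---
title: "Counting tillers by edge-based segmentation: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting tillers by edge-based segmentation: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culmcount)
```

## The problem

Tiller number — the count of individual shoots a grass plant produces — is a
yield-determining trait, and counting tillers by hand across a breeding
population of hundreds of plants is the bottleneck. A practical imaging
workflow clips every tiller to a uniform 2.0 cm length, spreads the
clippings on a black velvet background, and photographs them from directly
above (3024 x 4032 px over roughly a 30 x 40 cm field of view, about 100.8
px/cm). The computational task is then to count green, slightly curved,
frequently overlapping line segments in an RGB image.

`culmcount` implements the desk-scale core of that workflow: a synthetic
scene generator with exact ground truth, the classical edge-based
segmentation counter used as the transparent baseline, detector-agnostic
post-processing (confidence filter, NMS, IoU matching, AP@50), annotation
IO, and the evaluation harness that quantifies counting accuracy by density
stratum.

## The synthetic scene model

`render_scene()` emulates the imaging conditions, not plant biology. Each
tiller is a constant-width stroke along a circular arc:

* length: 2.0 cm x px/cm, jittered +/- 2% (clipping is uniform by design);
* width: uniform in 8–16 px at full scale (~0.8–1.6 mm, the realistic
  diameter range for bentgrass tillers at these optics);
* curvature: uniform in [0, 0.003] rad/px with random sign — a total bend
  of up to ~35 degrees over the segment, matching the near-straight look of
  2 cm clippings;
* color: HSV with hue uniform in 85–145 degrees (green band), saturation
  0.5–0.95, value 0.35–0.9;
* background: near-black triplet (8, 8, 10) with Gaussian sensor noise
  (sd 2), emulating light-absorbing velvet;
* debris: Poisson-distributed pale stubs and ellipses no longer than a
  quarter tiller length, flagged `is_tiller = FALSE` — the misclassification
  source that motivated the 2 cm clipping standard. Debris frequency on a
  well-prepared sample is not something anyone has quantified, so the
  default rate of 3 per scene is a stated choice, not a fitted one.

Two placement modes bracket the difficulty range. `disjoint` keeps instance
masks separated by at least 12 px (full scale) via rejection sampling —
the idealized, fully separable case; an infeasible density raises an
explicit placement error. `free` drops instances independently, so overlap
arises naturally at exactly the rate geometry dictates; this is the mode
that reproduces density-dependent undercounting.

Ground truth is exact by construction: the generator records every
instance's rendered pixels, so bounding boxes are tight bounds of actual
foreground, not approximations. Boxes are 0-based, half-open,
`[x_min, x_max) x [y_min, y_max)`, origin top-left — one convention across
the whole package.

A global `scale` factor shrinks the frame and all lengths proportionally so
that batches run quickly; `scale = 1` is full geometry. Widths are floored
at 4 px after scaling: a thinner stroke cannot survive any 3 x 3 erosion
and corresponds to no physical tiller at the emulated optics, so allowing
it would change the object model rather than the resolution. The
disjoint-mode gap is floored at 6 px for the same reason: Gaussian
re-binarization plus 3 x 3 dilation under 8-connectivity can bridge up to
about 5 px, so a smaller gap would make "disjoint" scenes unseparable in
principle, changing the study condition rather than scaling it.

What the generator does *not* emulate: perspective and lens distortion,
specular highlights, shadows, JPEG artifacts, wilted or discolored tissue,
and the long-tailed clutter of real field samples. Passing tests on
synthetic scenes therefore demonstrate algorithmic correctness and the
geometry-driven failure modes (merging under occlusion), not photometric
robustness.

## The edge-based counter

`count_tillers()` is the classical five-stage baseline:

1. **Hue threshold** (`hue_mask`): HSV conversion; foreground iff hue in
   [70, 170] degrees *and* saturation >= 0.25 *and* value >= 0.15. The
   saturation/value guards exclude near-black pixels whose hue is
   numerically undefined. Hue is always expressed on the 0–360 circle;
   any library-internal encoding is an IO concern.
2. **Denoise** (`denoise`): 3 x 3 erosion removes sub-element specks, then
   a 5 x 5 Gaussian (sigma 1) smooths the 0/1 raster, re-binarized at 0.5.
3. **Canny edges** (`edge_map`): Sobel gradients, non-maximum suppression
   with ties kept (a binary step yields equal magnitudes on both sides of
   the transition, so keeping ties produces a contiguous two-pixel boundary
   band rather than a fragile one-pixel ridge), hysteresis at 50/150 on the
   0–255 raster, then 3 x 3 dilation to strengthen continuity.
4. **Hole filling and labeling** (`count_regions`): interior holes are
   filled so each closed outline collapses to one region; components
   smaller than 25 px (full scale, scaled by `scale^2`) are discarded;
   8-connectivity by default.
5. The count is the number of surviving components.

The five stages are standard; their settings are not, and no canonical
values exist for this imagery. The defaults above are conservative
implementation choices, all exposed in `edge_params()`.

Two design choices deserve justification. Counting is performed on the
hole-filled dilated edge raster, so the structural argument for
*undercounting* goes through: every connected component of the union of
instance silhouettes contains at least one instance, and no instance
contributes more than one component, hence `predicted <= true` on
debris-free scenes — merging can only reduce the count. Whether the
original workflow counted edge components or filled regions is not
documented; filled regions make the undercount law provable and match the
"each distinct segmented region" description. Second, the tie-keeping
non-maximum suppression makes outlines closed in practice, which both the
exactness property (separable scenes counted exactly) and the undercount
property depend on.

The counter's characteristic failure is geometric: in free-overlap scenes
the probability that a tiller touches another grows with density, touching
silhouettes merge into one region, and the count falls increasingly short.
Stratified by true count — low (< 150), medium (150–400), high (> 400) —
the predicted-versus-true regression stays near the identity line at low
density and degrades monotonically, which is exactly the behavior the
evaluation harness is built to expose.

## Detector post-processing

The detection layer never runs a network; it evaluates any detector's
`(box, score)` output. Defaults follow the workflow's fixed conversion
settings: score >= 0.5 kept (inclusive — the convention when a bare
"threshold" is stated), greedy NMS suppressing at IoU strictly above 0.7
with score ties broken by input order (determinism), and matching at
IoU >= 0.5 with greedy best-IoU assignment per descending score, mirroring
the COCO evaluator rather than Hungarian assignment. `average_precision()`
offers both the COCO 101-point interpolation (default, matching the cited
tooling) and exact all-point integration of the precision envelope; with a
single class, AP@50 and mAP@50 coincide. Zero ground truth makes AP
undefined and returns `NaN` with a warning rather than a silent 0.

## Augmentation bookkeeping

The four label-preserving operators (`hflip`, `vflip`, `rotate45`,
`hsv_channels`) exist for their accounting identity: each preserves
per-scene instance counts, so `expand_dataset()` over `k` ops with
originals kept multiplies the instance total by `k + 1` exactly — e.g.
21,603 instances across 90 scenes become 64,809 with two ops. `rotate45`
rotates onto an expanded canvas (ceiling of the rotated extent,
background-filled) precisely so no instance can be cropped away; the cost
is that canvas dimensions grow under composition, and that the
corner-transformed axis-aligned box of a thin diagonal stroke is a loose
bound (the box still *contains* the instance, which is the invariant the
tests assert). Rotation resamples the image bilinearly but transforms box
corners exactly.

## Evaluation conventions

`regress()` fits ordinary least squares of predicted on manual counts with
intercept (the conventional reading of a goodness-of-fit R²; an
identity-line R² is also computed and exposed as `r2_identity`). Error
metrics: RMSE; NRMSE = 100 x RMSE / (max − min of manual counts) — the
range normalizer is the only convention consistent with the reported
error-table arithmetic this package reproduces in its tests; MAPE over
records with manual > 0 (zero-truth records are excluded with a warning);
MAE; and bias as mean(predicted − manual), negative under systematic
undercounting. `stratified_report()` partitions records by `regime_of()`
(low < 150, medium 150–400 inclusive on both ends, high > 400; the three
strata partition the non-negative integers).

`population_summary()` uses linear-interpolation (type 7) quantiles,
Fisher–Pearson moment skewness g1, and reports kurtosis in the Pearson
convention (m4/m2², normal = 3) as the headline — matching how a
near-normal count distribution with kurtosis ~2.6 is described as having
moderate tail weight — with the excess variant alongside.

## Numerical and degenerate-input choices

* Connected components: 4-connectivity labeling merged across diagonal
  contacts by union-find gives 8-connectivity; both exposed.
* Confidence filtering is inclusive (>=); NMS suppression is strict (>);
  both stated so boundary cases are deterministic.
* `regress()` refuses n < 3 and zero truth range; `population_summary()`
  refuses n < 4 (a fourth moment of fewer points is not meaningful).
* Scene rendering, batching, splitting and benchmarking all take explicit
  seeds; per-scene seeds derive from the master seed, so any batch is
  reproducible bit-for-bit.

## Problem sizes

The test and benchmark batch sizes are the package's own choices: the
stratified accuracy reproductions use 30 scenes per stratum at scale 0.5
(the smallest geometry at which the full-scale morphology parameters
transfer unchanged), and the 100-scene property suites (undercount law,
exactness on separable scenes) run at scale 0.25, where instances remain
resolvable thanks to the width floor. Larger frames change runtimes, not
conclusions.

## Known limitations

* The counter's accuracy claims transfer to real imagery only to the
  extent the scene model holds (uniform lighting, clean background,
  saturated green tissue); real-scene hue windows may need retuning.
* Canny thresholds and kernel sizes are fixed defaults, not adaptive;
  Otsu-style thresholding is an explicit non-goal.
* Debris is modeled pale and non-green, so the default hue window rejects
  it; debris that *is* green (leaf tips) would inflate counts and is not
  modeled.
* AP evaluation is single-class; crowd annotations and IoU sweeps
  (0.5:0.95) are out of scope.

## A worked example

```{r example, fig.width = 5, fig.height = 5}
sc <- render_scene(scene_params(count = 12, overlap_mode = "disjoint",
                                debris_rate = 0, scale = 0.2, seed = 7))
ep <- edge_params(scale = 0.2)
count_tillers(sc$image, ep)  # exact on separable scenes

cfg <- list(regimes = list(low = list(n = 6, count_range = c(20, 149)),
                           medium = list(n = 6, count_range = c(150, 400))),
            scale = 0.2, seed = 11)
bench <- run_benchmark(cfg)
bench$by_regime$low$r2
bench$by_regime$medium$r2
plot(bench$by_regime$medium)
```
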