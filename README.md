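# culmcount

Counting grass tillers in top-down images of clipped shoot segments.

Tiller number per plant is a key yield trait in forage and turfgrass
breeding, and counting it by hand across a population of hundreds of plants
is slow enough to limit what gets phenotyped. A practical imaging workflow
clips every tiller to a uniform 2.0 cm, spreads the clippings on black
velvet, and photographs them from 45 cm above (3024 x 4032 px over ~30 x
40 cm, about 100.8 px/cm). `culmcount` provides the computational core for
building and evaluating counters on such images:

* **Synthetic scenes with exact ground truth** (`scene_params()`,
  `render_scene()`, `scene_batch()`): green, slightly curved,
  constant-width strokes on a noisy near-black background, with optional
  pale debris, controllable instance counts from tens to over a thousand,
  and either guaranteed-separated or naturally overlapping placement.
  Every instance's pixels and tight bounding box are recorded.
* **The classical edge-based counter** (`count_tillers()`): HSV hue
  threshold -> erosion + Gaussian smoothing -> Canny edges -> dilation ->
  hole filling and connected-component counting. Exact on well-separated
  instances; systematically undercounts as overlap merges silhouettes —
  the documented failure mode the evaluation harness quantifies.
* **Detector post-processing** (`filter_confidence()`, `nms()`,
  `detections_to_count()`, `match_detections()`, `average_precision()`):
  score filtering at 0.5, greedy NMS at IoU 0.7, COCO-style greedy
  matching at IoU 0.5, and AP@50 with 101-point or all-point
  interpolation — for evaluating any detector's `(box, score)` output.
* **Augmentation with exact bookkeeping** (`hflip()`, `vflip()`,
  `rotate45()`, `hsv_channels()`, `expand_dataset()`), annotation IO
  (LabelMe JSON, YOLO txt, COCO JSON), stratified train/val/test splits.
* **Evaluation harness** (`regress()`, `stratified_report()`,
  `population_summary()`, `run_benchmark()`): OLS of predicted on manual
  counts with R², RMSE, NRMSE (= 100 x RMSE / manual-count range), MAPE,
  MAE and bias, stratified by density regime (low < 150, medium 150–400,
  high > 400), plus quartile/skewness/kurtosis population summaries.

## Worked example

```r
library(culmcount)

# a separable scene: 12 tillers, guaranteed pairwise separation
sc <- render_scene(scene_params(count = 12, overlap_mode = "disjoint",
                                debris_rate = 0, scale = 0.2, seed = 7))
count_tillers(sc$image, edge_params(scale = 0.2))
#> [1] 12

# density-stratified benchmark of the edge counter
cfg <- list(regimes = list(low = list(n = 6, count_range = c(20, 149)),
                           medium = list(n = 6, count_range = c(150, 400))),
            scale = 0.2, seed = 11)
bench <- run_benchmark(cfg)
bench
#> Tiller counting benchmark (edge method): 12 scenes, scale 0.20, seed 11
#> Overall: Counting accuracy (edge), n = 12, manual-count range = 276
#>   fit: predicted = 38.554 + 0.358 * manual,  R^2 = 0.843
#>   RMSE 78.936  NRMSE 28.600%  MAPE 30.149%  MAE 57.917  bias -57.917
#> [low density] Counting accuracy (edge), n = 6, manual-count range = 103
#>   fit: predicted = 10.774 + 0.666 * manual,  R^2 = 0.965
#>   RMSE 21.810  NRMSE 21.175%  MAPE 17.190%  MAE 17.333  bias -17.333
#> [medium density] Counting accuracy (edge), n = 6, manual-count range = 127
#>   fit: predicted = 87.679 + 0.140 * manual,  R^2 = 0.849
#>   RMSE 109.481  NRMSE 86.206%  MAPE 43.109%  MAE 98.500  bias -98.500
#> Population counts: n = 12, range 22-133
#>   quartiles 71 / 102.5 / 113.75 (25th / median / 75th)
#>   skewness -0.80, kurtosis 2.66 (excess -0.34)
```

The low-density stratum tracks the identity line closely (R² = 0.97,
small negative bias), while the medium stratum shows the counter's
characteristic occlusion behavior: correlated but flattened predictions
with a large negative bias, because overlapping tillers merge into single
segmented regions and the count falls short. At `scale = 0.2` the relative
instance footprint is larger than at full geometry, so merging sets in
harder — the qualitative pattern, not the exact slope, is the point.

A thin command-line wrapper over the same functions ships with the
package (`generate`, `count-edges`, `postprocess`, `map50`, `augment`,
`split`, `evaluate`, `popstats`, `benchmark`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/culmcount.R", package="culmcount"))')" \
  generate --n 5 --count-range 20,149 --overlap disjoint --seed 1 --scale 0.25 --out scenes
```

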