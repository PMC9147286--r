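# bollcount

Counting cotton bolls in proximal RGB imagery, with full or weak
supervision.

The total boll count of a cotton plant is a primary yield-component trait
for breeders and growers, but counting bolls by hand does not scale, and
annotating enough training images for supervised detectors is the real
bottleneck: instance masks cost tens of seconds per boll, one point per
boll is roughly ten times cheaper, and a single present/absent label per
image patch costs a couple of seconds regardless of how many bolls it
contains. `bollcount` implements counting models across that whole
annotation-cost spectrum, plus everything around them: image tiling with
plant-level aggregation, VGG Image Annotator (VIA) import/export, the
repeated-runs evaluation protocol, and a seeded synthetic scene generator
so every stage is testable on a plain CPU.

## What is inside

* **Tiling** — `tile_image()` decomposes a plant image into non-overlapping
  square zero-padded tiles (default 500 px); `assign_points_to_tiles()`
  partitions point labels by half-open windows so per-tile counts always
  sum to the total; `aggregate_plant_count()` sums tile counts back to the
  plant; `stitch_tiles()` inverts the tiling exactly.
* **Annotations** — `read_via_export()` / `write_scenes()` speak the VIA
  JSON dialect (point and polygon regions); `derive_class_label()` and
  `bin_count()` derive presence/absence labels and the count bins
  (0, 1–5, 6–10, 11–15, above-15 = `dnc`, flagged and excluded from
  training); `balance_by_rotation()` augments sparse bins with exact
  90°/180°/270° copies.
* **S-Count** — fully supervised count regression: a convolutional
  backbone, N response maps from a 1×1 convolution (N = 6 default), a
  fully connected head, mean-squared-error training on point-label counts.
* **WS-Count** — weakly supervised: a presence-absence classifier (PAC),
  trained only on class labels, supervises a shared counter applied to 21
  multi-scale patches per tile (1 + 4 + 16). The training objective is a
  classifier-consistency term, `mean_b[(1-p_b)|c_b| + p_b max(0, 1-c_b)]`,
  plus a spatial-consistency term `|C1-C4| + |C1-C16| + |C4-C16|` over the
  per-scale totals. Ground-truth counts are never read (the trainer
  rejects them).
* **CountSeg** — weakly supervised density counting under image-level
  lower-count (ILC) supervision: shared features split between a
  classification branch and a nonnegative density map whose sum is the
  count, trained with `L = L_class + L_spatial + L_global` — exact counts
  inside the subitizing range [0, 10], a lower-bound hinge beyond it, and
  pseudo ground-truth peaks (count-capped local maxima of the confidence
  map) for localization. `peak_instances()` exports instance locations
  from the density map.
* **Evaluation** — `evaluate_model()` implements the protocol of K
  independently trained runs: RMSE per count bin as mean ± sd across runs,
  per-tile median-of-runs error histograms with the fraction of errors
  within ±3, least-squares calibration with R², bubble-plot data;
  `evaluate_plants()` runs tile → predict → sum at plant level. Results
  are tibbles with `tidy()`, `glance()` and `autoplot()` methods.
* **Synthetic scenes** — `generate_scene()` / `generate_dataset()` draw
  seeded scenes of bright soft-edged elliptical blobs on textured
  foliage-like backgrounds with occlusion, shadows, exact points/masks/
  counts, and the field-typical count-bin imbalance.
* **Pipeline** — `run_end2end()` (and the `inst/cli/weakcount.R` script)
  orchestrates tile → predict → aggregate → evaluate with config files,
  seed fan-out, and byte-reproducible reports.

All networks run on a small pure-R reverse-mode engine (im2col convolution
on BLAS, batch norm, pooling, residual blocks, SGD/Adam) whose gradients
are verified against finite differences in the test suite.

## Worked example

Train the supervised counter on a seeded synthetic benchmark (200 tiles of
64×64 px with 0–5 well-separated bolls), evaluate on 50 held-out tiles,
and count a full synthetic "plant" by tiling:

```r
library(bollcount)

cfg <- scene_config(image_height_px = 64, image_width_px = 64,
                    blob_radius_range_px = c(2.5, 5),
                    occlusion_probability = 0, seed = 101)
train <- scenes_to_tiles(generate_dataset(200, c(zero = 1/6, b1_5 = 5/6), cfg))
cfg$seed <- 102
test  <- scenes_to_tiles(generate_dataset(50,  c(zero = 1/6, b1_5 = 5/6), cfg))

model <- build_scount(scount_config(seed = 1, epochs = 20))
model <- train_scount(model, train[, c("image", "count")])

report <- evaluate_model(model, test)
report
#> <eval_report> 1 run(s); overall RMSE 0.447 +/- 0.000; 100.0% of errors within +/-3
#>   calibration: pred = 0.881 * truth + 0.107 (R^2 = 0.939)
#> # A tibble: 2 × 3
#>   bin   mean_rmse sd_rmse
#>   <fct>     <dbl>   <dbl>
#> 1 zero        0         0
#> 2 b1_5        0.5       0

plant <- generate_scene(scene_config(image_height_px = 128, image_width_px = 128,
                                     count_range = c(6, 12),
                                     blob_radius_range_px = c(3, 6), seed = 7))
plants <- tibble::tibble(plant_id = "plant_1", image = list(plant$image),
                         points = list(plant$points))
evaluate_plants(model, plants, tile_size_px = 64)$summary
#> # A tibble: 1 × 4
#>   plant_id truth mean_total sd_total
#>   <chr>    <int>      <dbl>    <dbl>
#> 1 plant_1      7          7        0
```

The overall RMSE is in bolls per tile; the calibration line compares the
median-of-runs predictions with the identity Y = X; the plant total is the
sum of per-tile predictions over the 2×2 tile grid, here matching the true
count of the synthetic plant.

The weakly supervised models train the same way from cheaper labels:
`train_wscount()` consumes only `image` + `class_label` (it errors if a
count column is passed), and `train_countseg()` consumes `image` + `count`
within the subitizing range only (it errors if point coordinates are
passed).

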