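# wingfa

Wing morphometrics and fluctuating asymmetry (FA) for paired insect wings.

## What it is for

The left and right wings of an insect develop as mirror images; small
random deviations from that symmetry — fluctuating asymmetry — are a
classical proxy for developmental instability under environmental stress.
In damselflies and dragonflies the wings form during the aquatic larval
stage, so adult wing asymmetry can record stress experienced in the water
(insecticides, altered hydrology, larvicide-driven food-web change).

`wingfa` implements the full analysis chain for ecotoxicologists and
morphometricians working with paired wing photographs or vectorized wing
geometries:

* **Segmentation**: binary wing image → outline polygon, membrane cells
  (white connected components), vein junctions (skeleton branch points),
  with proximal/distal section labels (`segment_wing()`, `assign_sets()`).
* **Descriptors**: per-cell area, perimeter, principal-axis length/width,
  circularity `4*pi*A/P^2`; whole-wing size variables; wing load
  (`cell_features()`, `wing_features()`, `wing_load()`).
* **Pairwise asymmetry**: mirror alignment, optimal (Hungarian)
  sister-cell and junction matching with a distance gate, and the
  asymmetry inventory — bidirectional NRMSE of cell traits, mean matched
  distances, outline distance, subtract values (count differences), wing
  size differences (`pair_asymmetry()`).
* **Shape FA**: generalized Procrustes analysis of 12-landmark
  configurations with a bilateral-symmetry decomposition into directional
  asymmetry and per-individual FA scores (`gpa()`, `fa_decomposition()`,
  `fa_scores()`), with TPS/CSV landmark IO.
* **Spatial maps**: per-cell asymmetry carried into a common wing frame,
  gridded 300 × 300 per group, treatment − control difference maps with a
  missing-aware Gaussian blur (`cmd_spatial()`, `build_group_grid()`,
  `difference_map()`).
* **Stressor statistics**: per-response GLMs (gaussian identity; Poisson
  log for counts), Type-II likelihood-ratio chi-square tests for the
  factorial design, predicted percentage changes with SEs
  (`run_full_analysis()`, `lr_chisq_tests()`, `percentage_change()`).
* **Synthetic data**: a ground-truth wing-pair and cohort generator with
  explicit asymmetry channels (junction jitter, cell-shape noise, outline
  noise, cell merges, directional offsets, regional injection) so every
  stage is testable without access to a real dataset
  (`synthetic_config()`, `generate_wing_pair()`, `generate_cohort()`,
  `render_wing_image()`).

The model at the core of the pairwise layer: for matched sister cells with
trait values `x_L`, `x_R`,

```
NRMSE = sqrt(mean((x_L - x_R)^2)) / mean(x_ref)
```

averaged over both comparison directions; for landmarks, the individual
asymmetry vector `a_i = L_i - reflect(R_i)` after Procrustes alignment is
split into the mean (directional) component and the residual FA component,
whose norm is the FA score.

## Worked example

Simulate a 2 × 2 mesocosm-style cohort in which "hydrology" increases wing
size by 10% and junction noise by 30%, then run the full analysis:

```r
library(wingfa)
cfg <- synthetic_config(cells_target = 120, seed = 42,
                        effect_map = list(hydrology = c(outline_length_mm = 1.1,
                                                        fa_position_sd_um = 1.3)))
co <- generate_cohort(cfg, data.frame(bti = c(0, 1, 0, 1),
                                      hydrology = c(0, 0, 1, 1), n = 15))
ca <- analyze_cohort(co, mode = "mesocosm")
ca$analysis
#> <stress_analysis> mode=mesocosm, 19 responses fitted
#>   9 significant stressor LR tests at alpha=0.05

subset(ca$analysis$lr_tests,
       response %in% c("wing_length", "mean_dist_junctions") & term == "hydrology")
#>             response      term chisq df        p
#>          wing_length hydrology  40.7  1 1.81e-10
#>  mean_dist_junctions hydrology  64.5  1 9.48e-16

subset(ca$analysis$pct_changes,
       response %in% c("wing_length", "mean_dist_junctions") & factor == "hydrology")
#>             response    factor level baseline_mean level_mean change_pct se_pct
#>          wing_length hydrology     1          19.6       21.5       9.57  0.357
#>  mean_dist_junctions hydrology     1         102.5      129.3      26.07  0.264
#>  se_delta_pct n_predictions
#>          1.37            60
#>          2.88            60
```

(`se_pct` is the within-group prediction-spread SE; `se_delta_pct` is the
delta-method SE of the percentage-change estimate itself.)

The injected +10% size effect is recovered as +9.6% on wing length (mm),
and the ×1.3 junction-noise effect appears as +26% on the mean matched
junction distance (µm) — the expected value once the independent
cell-shape noise floor is accounted for. A single pair's record:

```r
rec <- pair_asymmetry(co$pairs[[1]]$left, co$pairs[[1]]$right)
round(unlist(rec[c("nrmse_circularity", "mean_dist_junctions",
                   "subtract_cells", "wing_length")]), 3)
#>   nrmse_circularity mean_dist_junctions      subtract_cells         wing_length
#>               0.068              94.659               1.000              20.575
```

i.e. a 6.8% RMS circularity asymmetry across sister cells, a 94.7 µm mean
displacement of matched junctions, a one-cell count difference, and a
20.6 mm pair-mean wing length.

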