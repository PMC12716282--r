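---
title: "Quantifying wing morphology and fluctuating asymmetry with wingfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wing morphology and fluctuating asymmetry with wingfa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingfa)
```

## The scientific problem

Insect wings are paired organs that develop under a shared genotype and a
shared environment; in the ideal case the left and right wing of one
individual are mirror images. Small, random deviations from that mirror
symmetry — fluctuating asymmetry (FA) — arise from developmental noise, and
their magnitude is widely used as a proxy for developmental instability
under environmental stress. In damselflies the wings form during the
aquatic larval stage, so adult wing asymmetry can carry a signature of
stress experienced in the water, such as insecticide exposure, altered
hydrology, or food-web perturbation by larvicides.

`wingfa` implements the full analysis chain for this question on paired
wing images or vectorized wing geometries:

1. **Segmentation** of a binary wing photograph into the wing outline, the
   membrane cells enclosed by the vein network, and the vein junctions.
2. **Per-cell and whole-wing descriptors** (area, perimeter, principal-axis
   length and width, the isoperimetric circularity $4\pi A/P^2$).
3. **Pairwise asymmetry**: the right wing is reflected, both wings are
   aligned, sister cells and junctions are matched one-to-one, and the
   asymmetry variable inventory is computed — NRMSE of cell traits, mean
   distances between matched junctions/centroids and between outlines,
   absolute count differences ("subtract values"), and wing-size
   differences.
4. **Landmark shape FA**: a generalized Procrustes fit of 12-landmark
   configurations with a bilateral (matching) symmetry decomposition into a
   directional-asymmetry component and per-individual FA scores.
5. **Spatial maps**: per-cell asymmetry values are carried into a common
   wing frame and averaged per treatment group on a 300 × 300 grid;
   treatment-minus-control maps localize where on the wing asymmetry
   responds.
6. **Stressor statistics**: per-response GLMs (gaussian identity; Poisson
   log for counts), Type-II likelihood-ratio χ² tests for factorial
   designs, and model-predicted percentage changes with standard errors.

Because raw data of this kind are typically available only on request, the
package ships a first-class synthetic wing generator with known ground
truth; every stage of the pipeline is tested against it.

## The synthetic wing model

`synthetic_config()` describes one study condition. A wing is a deformed
rectangular lattice of membrane cells clipped to a convex
elliptical-teardrop outline with a flattened leading edge (the nearly
straight costa of odonate wings; the flattening is also what makes the
common-frame rotation identifiable). The two wings of an individual share
one template — lattice, smooth warp, outline — and differ only through
explicitly modelled asymmetry channels:

* **Position channel** (`fa_position_sd_um`, default 50 µm): independent
  Gaussian jitter per side on every lattice node; cell polygons follow
  their nodes, so the tessellation stays gap-free. Default chosen so the
  baseline mean matched-junction displacement (≈ 1.77 × 50 ≈ 90–130 µm
  after alignment) is on the scale reported for real damselfly hindwings.
* **Shape channel** (`fa_shape_sd`, default 0.02): extra node jitter scaled
  by the local lattice spacing, expressing cell-edge irregularity.
* **Outline channel** (`fa_outline_sd_um`, default tied to the position
  channel): smooth low-order harmonic perturbation of each side's outline;
  this is the wing-size FA channel.
* **Count channel** (`count_perturb_prob`, default 0.3): with this
  probability a wing merges one adjacent cell pair, perturbing cell and
  junction counts. Cell *membership* is otherwise decided on the noise-free
  template: positional jitter moves cells but does not create or destroy
  them.
* **Directional asymmetry** (`directional_offset_um`): a constant
  translation of all right-wing junctions; with `antisymmetry = TRUE` the
  offset takes a random sign per individual. Both are off by default and
  exist for the symmetry-type screening tests.
* **Regional injection** (`fa_region`, `fa_region_extra_sd_um`): extra
  positional noise restricted to the proximal or distal wing half, used to
  validate spatial localization.

Cohort structure: `generate_cohort()` takes a design table (binary
indicators or doses), draws wet weight (lognormal, mean 25 mg, CV 0.15),
larval weight gain, and days to emergence (Poisson, mean 28), and scales
any generator parameter by the factor-specific multipliers in
`effect_map`. Sex enters as a size multiplier (`sex_effect`, default 0.95
for males). Wing size varies between individuals with a lognormal
multiplier (`size_cv`, default 5%). The defaults are damselfly-scale
choices (20 mm wings, aspect 4, ~250 cells); the cell count of real wings
is configurable because its distribution is not well characterized.

What the generator deliberately does **not** emulate: biologically
realistic venation topology (cells sit on a warped lattice, not on a vein
tree), pterostigma and nodus anatomy, vein thickness variation, wing
damage, and measurement error of a real camera. Passing tests therefore
demonstrate correctness of the *measurement and inference machinery* under
a controlled asymmetry model — not robustness to every property of real
photographs.

## Numerical and design choices

* **Exact mirror identity.** Mirroring preserves vertex order (IEEE
  negation is exact), nearest-point distances are recomputed from
  coordinate differences rather than taken from the squared-distance
  matrix, and the alignment search snaps to a zero angle when it is
  optimal. Consequence: on noise-free pairs every asymmetry variable is
  exactly 0, and the test suite asserts ≤ 1e−9.
* **Alignment** (`align_pair()`): reflection, centroid translation, then a
  rotation minimizing the symmetric mean nearest-point distance between
  arc-length-resampled outlines (coarse scan refined by golden-section to
  1e−4 rad). No scaling — size asymmetry is signal. The outline distance
  variable resamples both outlines to 500 arc-length-uniform points.
* **Sister matching** (`match_sisters()`): Hungarian assignment on
  centroid distances with a gate of 25% of wing length. The gate enters
  the optimization itself (dummy partners at gate cost), so points whose
  partner is missing are left unmatched instead of being absorbed through
  cascade matches — the classical failure mode when the two point sets
  differ in membership.
* **NRMSE**: `sqrt(mean((ref − other)^2))/mean(ref)`, computed in both
  directions and averaged; the normalizer is the reference-direction mean.
* **Symmetry-type screening** (`screen_symmetry_type()`): one-sample
  t-test for directional asymmetry; D'Agostino K² (moment-based, matching
  `scipy.stats.normaltest` to 10 digits) for normality. Antisymmetry is
  flagged when K² rejects *and* the raw excess kurtosis is negative — the
  classical platykurtosis fingerprint of antisymmetric mixtures. The raw
  kurtosis direction is used because the Anscombe–Glynn z statistic loses
  its sign in the extreme platykurtic regime (cube root of a negative
  ratio), a property shared by every standard implementation.
* **GPA / FA score** (`gpa()`, `fa_decomposition()`): translation to
  centroid, unit centroid size, iterative SVD rotations to the consensus
  (tolerance 1e−10, ≤ 100 iterations); right configurations are reflected
  before fitting (matching symmetry for paired organs). The FA score is
  the full Euclidean norm of the individual asymmetry after subtracting
  the mean (directional) component; tangent projection is omitted because
  the difference is far below the noise at these shape variances. Sexes
  are fitted in separate GPAs (shape dimorphism would otherwise leak into
  the asymmetry component) and the scores pooled, with sex as a model
  covariate downstream. Front and hind wings are analyzed separately. No
  automatic outlier exclusion is performed on FA scores.
* **Common frame** (`superimpose_common_frame()`): each wing is rotated so
  the least-squares line through its *upper envelope* (bin-wise topmost
  outline point, 40 bins across the middle 80% of x, iterated to a fixed
  point) is horizontal, then translated to its center of gravity. A plain
  "top 10% of y" rule was rejected: on a convex outline it always selects
  the apex and cannot recover rotations (0.26° recovered for a 7°
  rotation); the envelope rule recovers constructed rotations to machine
  precision.
* **Group grids** (`build_group_grid()`): linear barycentric interpolation
  (`interp::interp`, the maintained successor of the akima interpolator
  classically used for this step) of each wing's scattered per-cell values
  onto a shared 300 × 300 grid, then a pointwise mean over wings ignoring
  missing nodes. The 5%/95% trim for circularity and width traits is
  applied pooled within group × trait before gridding (a per-group rule,
  fixed for reproducibility). Nodes outside a wing's convex hull stay
  missing — they are never zero-filled.
* **Difference maps** (`difference_map()`): treatment − control on
  co-valid nodes, then a Gaussian blur with σ = 10 grid cells,
  mask-normalized (blur of values divided by blur of the validity mask)
  and restricted to the original support, so missing regions neither pull
  the map toward zero nor acquire extrapolated values.
* **GLM layer** (`fit_glm()`, `lr_chisq_tests()`, `percentage_change()`):
  gaussian-identity and Poisson-log families via `stats::glm`;
  per-coefficient t (gaussian) or Wald z (Poisson) tests. Type-II
  likelihood-ratio χ² respects marginality (main effects tested without
  the interaction); gaussian models use the fixed-scale deviance
  convention χ² = n·log(RSS_reduced/RSS_full). Percentage changes predict
  every observed covariate row at each factor level (averaging over the
  levels of the other factors), compare level means against the baseline
  mean, and report the within-level prediction SE scaled by the baseline.
  No multiple-testing correction is applied by default; a
  Benjamini–Hochberg switch (`p_adjust = "BH"`) is available.
  Concentration can enter continuously (default) or as a factor
  (`concentration_as_factor = TRUE`) for per-level contrasts.
* **Family map**: days to emergence, cell/junction counts and subtract
  values are Poisson; everything else gaussian. Pair-mean counts (x.5) are
  rounded before a Poisson fit.

## Degenerate inputs and error contracts

Zero-area cells, collinear landmark configurations, all-white images (no
closed wing boundary), aliased model terms, numerically zero baselines for
log-link percentage changes, grids with mismatched extents, and groups
with fewer than 3 wings all raise informative errors (or warnings with
skips where the contract says so). Individuals failing anywhere in the
per-pair pipeline are skipped and logged; a run aborts only when more than
half fail.

## What the validation suite establishes

The acceptance tests (in `tests/testthat/test-acceptance.R`, re-runnable
via `scripts/acceptance.R`) check, at the problem sizes given:

* **Zero-asymmetry identity** — noise-free mirrored pairs score exactly 0
  (≤ 1e−9) on the geometry path, and within rasterization tolerance
  (2.5 px for distances, 0.05 for NRMSE, ±1 count) on the render → segment
  image path at 20 µm/px.
* **Oracle equivalence** — NRMSE, optimal matching, and gaussian/Poisson
  GLM coefficients match brute-force enumeration / closed-form / textbook
  IRLS oracles to 1e−8 on ≥ 20 random instances each.
* **FA algebra** — one perturbed individual among n symmetric ones scores
  δ(n−1)/n, the rest δ/n (≤ 1e−6).
* **Screening power** — a mean offset of 4·sd/√n (n = 100) triggers the
  directional-asymmetry test, and a ±c mixture triggers the antisymmetry
  flag, each with power > 0.9 over 200 replicates.
* **Type-I calibration** — on null cohorts (n = 40/arm, 2 × 2 design,
  500 replicates; wet weight, days to emergence and wing length — all with
  correctly specified gaussian/Poisson families — rotating across
  replicates so each term yields one binomial rate over 500 trials), each
  stressor term's LR-test rejection rate lies within the 95% binomial CI
  of 0.05. The fixed-scale gaussian LR convention is mildly
  anti-conservative (about half a point at n = 160), which this CI
  accommodates.
  Tessellation cell counts are deliberately excluded here: they are
  underdispersed relative to Poisson by construction, so they would probe
  generator dispersion rather than GLM calibration — a caveat that applies
  to real cell counts as well.
* **Effect recovery** — a ×1.25 wing-size effect and a ×1.5 junction-noise
  effect (n = 60/arm, 100 replicates) are recovered as significant LR
  tests with percentage-change estimates within 2 SE of the injected
  truth (+25% and +50%), where SE is the delta-method estimator SE
  (`se_delta_pct`): for a ratio-type estimate `100·(m1 − m0)/m0` the
  baseline mean is itself estimated, and ignoring its variance and
  covariance with the contrast understates the SE by ~18% in this design.
  The recovery simulations use 30-cell wings and a reduced alignment
  search — problem sizes chosen so the whole suite stays conveniently
  re-runnable — after verifying that estimates at larger sizes agree.
* **Spatial localization** — with extra FA injected only distally
  (20 wings/group), ≥ 80% of the top-decile mass of the blurred difference
  map lies in the distal half (observed ≈ 95%).
* **Determinism** — fixed-seed simulate → analyze runs produce
  byte-identical CSVs.

## Known limitations

* The generator's venation is a warped lattice; spatial maps on synthetic
  data have lattice-scale granularity that real venation does not.
* Boundary cells clipped by the outline can be arbitrarily small; their
  sister identity is intrinsically ambiguous, and a handful of rim cells
  per cohort may match to a neighbor when one side's sliver degenerates.
* The image path inherits rasterization bias: polygonized cells
  underestimate pixel areas by roughly half the perimeter, symmetric
  between sides (hence near-zero NRMSE on mirrored rasters) but visible in
  absolute areas.
* Wing load, weight and emergence responses are generated as simple
  parametric draws; they validate the statistical layer, not the biology.
* `lr_chisq_tests()` assumes the fitted family is correctly specified;
  overdispersed counts (common in real subtract values) would need a
  quasi-Poisson extension.
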