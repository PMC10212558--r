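---
title: "Quantifying brain cytoarchitecture from serial sections: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying brain cytoarchitecture from serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoarch)
```

## The problem

Serial block-face imaging of whole mouse brains (serial two-photon
tomography, STPT) produces one optical section every 100 µm. In the
background autofluorescence channel, lipid-rich neuropil fluoresces while
cell nuclei absorb, so nuclei appear as dark, round objects — a staining-free
readout of cellular anatomy. Given such sections plus pixel-aligned atlas
label rasters, `cytoarch` estimates, per brain and per region, the three
quantities that define a region's cytoarchitecture: volume V (mm³), cell
density D (cells/mm³), and cell count N = V·D — and then compares them
across hemispheres, sexes, and strains over a population of brains.

Sections sample the tissue sparsely (each optical plane is ~1.5 µm thick in
a 100 µm gap), so a 2D detection count must be converted to a 3D density.
That conversion, and everything needed to trust it at population scale
(detection, region assignment, QC, batch handling, statistics), is what this
package implements.

## The slab model

We assume cells in a region are approximately equi-radius spheres. A sphere
of radius `r` whose centre lies `Δz` from the optical plane contributes
signal iff `|Δz| <= r + d/2`, where `d` is the optical depth of field. The
cells detected on a region's cross-section of area `a_s` therefore originate
from a slab of volume

    v_s = a_s * (2R + d),     rho_s = n_s / v_s,

with `R` the regional cell radius and `n_s` the detected count. Per region,
volume is the trapezoid sum of areas over adjacent sections
(`region_volume`), the count is the density-weighted trapezoid sum
(`region_count`), and overall density is `D = N / V` (`region_density`), so
`N = V * D` holds exactly by construction.

**Why the 90th radius percentile.** Measured in-plane radii are chord radii:
a cell centred off-plane projects a disk of radius
`sqrt(r^2 - max(0, |Δz| - d/2)^2)` (`apparent_radius`). The chord
distribution therefore understates the true radius, and the slab thickness
`2R + d` needs the *full* radius. A cell shows its full radius whenever
`|Δz| <= d/2`, which happens with probability `(d/2) / (r + d/2)` among
visible cells — about 16% for r = 4 µm and d = 1.5 µm. Because that
exceeds 10%, the 90th percentile of chord radii converges to the true radius
for nuclei up to `9 d / 2 = 6.75` µm radius, comfortably covering the
observed 3.5–4.75 µm range. This is why the estimator is nearly unbiased at
these parameter values (the test suite verifies mean |relative error| < 3%
over 20 phantom replicates), and why using the 50th percentile instead
yields a thinner slab and systematically larger densities and counts — while
leaving the rank order of regions unchanged (also under test).

**Edge sections.** A section at the very end of a region's extent sees only
half a slab, biasing its `rho_s` down. Sections where a region is annotated
but no cell is detected contribute density zero yet still bound volume
segments; regions present in a single section get V = 0 and a
`single_section` flag rather than a fabricated volume.

## Parameters and defaults

| Parameter | Default | Units | Role |
|---|---|---|---|
| `pixel_size` | 0.35 | µm/px | lateral image scale |
| `depth_of_field` | 1.5 | µm | axial extent of the optical plane |
| `section_gap` | 100 | µm | anterior–posterior section spacing |
| `tile_px`, `overlap_px` | 312, 20 | px | tiling of sections for detection |
| radius percentile | 90 | – | regional cell radius for the slab |
| `window_px` | 64 | px | coverage window for dense/sparse splits |
| `brightness_min` | 25 | /255 | dark-brain exclusion |
| `outlier_z`, `mad_scale` | 3, 1.4826 | – | robust count-outlier rule |
| `max_outlier_regions` | 3 | regions | artifact-brain exclusion |
| `min_region_median_volume` | 0.3 | mm³ | small-region exclusion |
| `min_region_median_count` | 500 | cells | low-count exclusion |
| `max_lr_diff_frac` | 0.155 | – | hemispheric-imbalance exclusion |
| `max_brightness_count_corr` | 0.3 | – | brightness-confound exclusion |
| `target_median_volume` | 380 | mm³ | batch-correction target |
| `effect_threshold` | 5 | % | dimorphism volcano flag |
| `q_threshold_dimorphism` / `strain` | 0.01 / 0.05 | – | FDR flags |
| `svm_C`, `svm_train_frac`, `svm_repeats` | 100, 2/3, 100 | – | sex classifier protocol |
| `corr_sig_abs` | 0.14 | – | V–D correlation significance mark |

The stride between tiles is `tile_px - 2 * overlap_px = 272` px: "overlap of
20 pixels on each side" is read as each interior seam being covered twice,
with edge tiles anchored to the image border (overlapping more than 20 px)
rather than padding mid-image. MAD·1.4826 estimates the SD under normality
(1/Φ⁻¹(0.75)); the count-outlier rule is one-sided because the targeted
artifact (resolution degradation) only ever inflates counts.

## The detector contract

The published analysis used a trained segmentation network; network training
is out of scope here, so detection is a *contract*: any function mapping a
grayscale tile to a boolean mask can be plugged into `detect_section` /
`detect_brain`. The shipped reference implementation (`detect_nuclei`) is
classical: Gaussian smoothing (σ = 1 px, replicate boundary — circular
boundary wraps dark content around tile borders and fabricates seam
objects), a threshold a fixed contrast (20 levels) below the tile median,
watershed splitting of touching blobs on the distance map, and a ≥5 px area
gate. Tiles whose median is below 30/255 are declared unusable and return an
empty mask with a warning, mirroring the dark-brain QC logic at tile scale.
Masks are stitched by pixelwise OR (idempotent and order-independent; the
OR is also the whole answer to de-duplicating detections in overlap strips).
Connected components use 8-connectivity; morphology records area, perimeter,
and the circle-equivalent diameter `2*sqrt(area/pi)*pixel_size` — "diameter"
is not otherwise well defined for an arbitrary mask component.

On phantom sections with non-overlapping disks (≥4 px apparent radius,
contrast 80 levels, noise σ = 5) the reference detector reaches recall ≥
0.95 at a false-positive rate ≤ 0.02 (tested). Where nuclei touch, the
watershed split is imperfect and merged detections bias counts down — the
same direction as the published detector's known undercount relative to
nuclear staining — so full-path density estimates on dense regions are
expected to sit below seeded truth; the estimator-level guarantees are
therefore stated with detection bypassed (ground-truth visible cells).

## Region assignment and dense/sparse splits

Cells take the label-raster value at their centroid; centroids on
unannotated pixels (label 0) are dropped but counted, so
`assigned + dropped = detected` is auditable. Hemispheres split at the
vertical centre column of the raster, with exact midline ties assigned right
(arbitrary but fixed; phantoms are built symmetric).

Where an atlas does not separate a dense band from its sparse surround
(e.g. a pyramidal layer), each cell gets a *coverage* value — the count of
mask pixels in a 64×64 px window centred on it, computed on the post-stitch
mask, clipped (not rescaled) at image borders — and 1D 2-means splits the
cells into dense and sparse clusters (`split_dense_sparse`; for 1D data
k-means is exactly the optimal single threshold, which is the test oracle).
Subregion outlines come from rasterizing cluster centroids, closing with a
3 px disc, and discarding components under 500 px (both exposed in
`coverage_config`; no principled values exist, so they are configuration,
not constants). Coverage separates the two populations only when the window
holds enough cells for its count noise to be small relative to the density
contrast; the validation fixture uses a 128 µm window (64 px at 2 µm/px) on
a 250 µm band embedded in sparse tissue on all sides, where a 6:1 density
ratio yields >90% correct assignment. Narrow bands or windows reaching
outside the tissue dilute the contrast and degrade the split.

## QC order and batch correction

Rules run in a fixed order, each on the survivors of the previous one: dark
brains → artifact brains → small/low-count regions → left/right-imbalanced
regions and brightness-correlated regions. "Median cell count across
sections smaller than 500" is ambiguous between per-section medians and
per-brain totals; the literal per-section reading is the default
(`count_rule = "section_median"`) with the total-count interpretation
switchable. The hemispheric rule averages the per-brain fraction
`|N_L - N_R| / (N_L + N_R)`. Batch correction multiplies each brain's
volumes by `target / median(batch volumes)`; densities are recomputed as
N/V and counts are untouched — so the correction can never change a count,
which the tests assert bitwise.

## Population statistics

All group comparisons are two-sided Wilcoxon rank-sum tests (exact when
sample sizes and ties permit; validated against full enumeration of the U
distribution for small samples), with Benjamini–Hochberg adjustment applied
within each (variable, qualifier) family of regional tests — matching the
one-volcano-per-panel presentation. Effects are median percent differences;
laterality uses the symmetric percent difference
`100 (L - R) / ((L + R)/2)` per brain, summarized by the median and the
fraction of brains left-biased. The laterality screen drops regions at or
below 0.05 mm³ and acronyms matching `(?<![0-9])1$|6b$` (cortical layer 1
and 6b, whose atlas registration is least reliable); the pattern is
configuration.

The sex classifier is a linear soft-margin SVM (C = 100) on z-scored
regional features over 100 stratified 2/3–1/3 splits; feature standardization
is required for hyperplane weights to be comparable across regions and is
switchable. Ranking is by mean |weight| across repeats; the incremental
curve retrains on the whole dataset adding one top region at a time and
reports training accuracy as-is (it is not guaranteed monotone).
Region-to-region similarity is the Pearson correlation matrix across brains;
the accompanying 2D map uses classical multidimensional scaling on
1 − correlation distances — a deterministic embedding, chosen because the
map is illustrative plumbing while the correlation matrix is the tested
contract.

## What the phantom generator emulates — and what it does not

`generate_phantom_brain` places cells by a homogeneous Poisson process at
region densities of 1–6 ×10⁵ cells/mm³ (the observed regional range), with
nucleus radii ~N(4, 0.25²) µm (diameters 7–9.5 µm), renders sections at
100 µm with the slab visibility rule, background 120 / nucleus 40 / noise
σ = 5 on the 8-bit scale (so default brains pass the brightness QC at 25 and
fixtures can violate it on demand), and returns exact ground truth. An
optional lateral hard-core distance produces non-overlapping-disk sections
for detector benchmarking. `simulate_cohort` generates population tables
directly: lognormal inter-individual noise (volume CV 5%, matching the
~4.5% whole-gray dispersion of real cohorts; per-region density CV 8%, the
regime in which a rank-sum screen at n = 40/group reliably flags 15%
effects at q < 0.01 — the generator's designed sensitivity), a shared
brain-level density factor with hemisphere-specific technical noise (CV 3%,
well under the 15.5% L/R exclusion bound), cyclic batch assignment with
volume offsets (reciprocals of correction factors ≈ 1.064/1.032/1.008), and
seeded sex, strain, and lateral effects of configurable size.

Not emulated: autofluorescence texture, vasculature, or tissue-composition
contrast differences; non-Poisson (packed) cell arrangements in the densest
layers; registration error between image and label raster; truncation of
anterior/posterior structures. Real per-region density dispersion is larger
(~14% at whole-brain level), so statistical power on real data is lower at
equal n than on these phantoms — passing the power tests here demonstrates
correctness of the machinery, not field sensitivity.

## Numerical choices and degenerate inputs

- Percentiles use linear interpolation (type-7 quantiles).
- 2-means restarts 10× under a fixed seed; identical coverage values
  produce no split (all sparse, warning) rather than an arbitrary one.
- Zero-MAD regions cannot define outliers and are skipped with a warning.
- `rho_s = 0` when `n = 0`; cells with positive count on zero annotated
  area are an error, not a silent drop.
- Region volumes sum only over *consecutive* present section pairs; gaps in
  coverage contribute nothing.
- All randomness flows from explicit seeds through a restore-on-exit RNG
  wrapper, so identical seeds give bit-identical phantoms and pipelines
  (manifest checksums are compared in tests).
- Pipeline configuration is YAML (nested blocks mirroring the config
  constructors) — the natural key-value format in the R ecosystem; unknown
  keys are errors, not silent ignores.

## Known limitations

The chord-radius argument above fails for nuclei larger than ~6.75 µm
radius, where the 90th percentile underestimates the true radius and
densities inflate. The watershed reference detector under-splits at
densities where disks routinely touch. The dense/sparse split assumes
exactly two coverage populations (k is fixed at 2). Volume estimation
cannot resolve structure finer than the 100 µm gap, and single-section
regions are flagged rather than estimated. None of the QC thresholds are
derived from a noise model — they are field conventions exposed as
configuration.
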