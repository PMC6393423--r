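---
title: "Methods: tumor morphometry and cohort statistics in xenometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor morphometry and cohort statistics in xenometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenometry)
```

`xenometry` measures the standard quantitative endpoints of subcutaneous
xenograft tumor studies. This vignette describes the models and procedures
behind each stage, the parameters that matter, the synthetic-data
generators used for validation, and the numerical conventions the package
commits to. Throughout, rasters are matrices indexed `[row, column]` with
origin top-left; exported coordinates are 0-based `(x, y)`; the pixel is
the unit of computation and a physical pixel edge (default 1.3 µm, typical
of a 40× digital microscopy setup) travels as metadata only.

## Necrosis segmentation and quantification

Necrotic tumor tissue on an H&E section is pale and nucleus-free; viable
tissue carries dense, dark, hematoxylin-stained nuclei on an eosin-pink
background. `segment_necrosis()` encodes exactly this contrast through two
feature maps, both Gaussian-smoothed at a common scale σ (default 8 px,
roughly a nucleus-spacing so the nuclear indicator integrates to a local
density):

- a *nuclear density* map: the smoothed indicator of nuclear-stain pixels,
  defined by blue-over-red channel dominance (hematoxylin and DAB are both
  far less red-dominant than eosin);
- a *pallor* map: smoothed luminance (Rec. 601 luma).

Both maps use normalized convolution restricted to the tumor mask — the
smoothed value at a pixel is the Gaussian-weighted mean over tumor pixels
only — so the white slide background can never leak into tissue near the
tumor border.

A tumor pixel is called necrotic when its nuclear density is below an Otsu
threshold *and* its pallor is above an Otsu threshold. Otsu's method always
finds a split, even in a unimodal map, so each threshold carries an
absolute guard: the density threshold is capped at `dens_cap` (default
0.10 — necrotic tissue has essentially zero nuclear cover after smoothing,
while viable tissue sits well above 0.1) and the pallor threshold is
floored at `lum_floor` (default 0.75 on the 0–1 scale — between smoothed
viable tissue, ≈0.64 under the default stain palette, and necrotic tissue,
≈0.88). On a fully viable section the guards prevent Otsu from
hallucinating a necrotic class. The raw call is regularized by
morphological opening then closing with a disk brush (radius 3 px) and
removal of connected components below 64 px — single nuclei dropouts and
stain speckle, not necrotic foci, at 1.3 µm/px. A section whose tumor
luminance has essentially no variance (SD < 0.001) is flagged degenerate
and returns 0% with a warning rather than an arbitrary Otsu split.

`percent_necrosis()` forms `100·|necrosis|/|tumor|` from the integer pixel
counts before the single final float division, so the percentage is
bit-identical across platforms.

## Box-counting fractal dimension

`box_count(mask, scales)` partitions the bounding box of the foreground
into an axis-aligned grid of ε×ε cells anchored at the bounding box's
top-left corner — one fixed offset, ragged cells allowed at the right and
bottom edges — and counts occupied cells. A single anchored grid is the
simplest convention and keeps counts integer-exact and trivially testable
against a brute-force cell scan; offset-averaging variants reduce variance
but break that exactness and are deliberately not the default.

`fractal_dimension()` fits ordinary least squares of `ln N(ε)` on `ln ε`
and reports the negated slope with its standard error and R². Default
scales are the powers of 2 from 2 up to `floor(min_side/4)`; the upper
bound keeps the ladder out of the saturated regime where a handful of
boxes covers everything and the local slope collapses. At least 4 scales
are required for the fit to mean anything. For lattices built by b-fold
subdivision (Mandelbrot percolation below), `scale_base = b` replaces the
dyadic ladder with powers of b, aligning box edges with the construction.
The dimension is reported positive; a fitted value outside [0, 2] (beyond
0.05 numerical slack) raises an error rather than being clipped, since it
indicates a degenerate input, not a measurement. The dimension is computed
on the necrosis mask alone — black-on-white necrotic pattern — not
relative to the tumor outline.

## Concentric zonal partition and Ki67 scoring

Proliferative activity in xenografts concentrates at the tumor border,
where space for growth is available, so scoring is stratified into an
outer region holding 20% of the cross-sectional area, an intermediate 30%,
and an inner 50%. `partition_zones()` defines concentricity by *distance
rank*: every tumor pixel gets its Euclidean distance to the nearest
background pixel (the raster is padded with a one-pixel background ring
first, so the image border counts as boundary), pixels are sorted by
`(distance, row, column)`, and the sorted sequence is cut at
`round(0.2·A)` and `round(0.5·A)`. This yields realized fractions exact to
one pixel for arbitrary tumor shapes — not just disks — and the
lexicographic tie-break makes the partition bit-reproducible. Zero-area
zones from degenerate fraction triples are allowed. Euclidean (not
city-block) distance is used so the zones are rotation-robust annuli on
round tumors; on a disk of radius R the outer zone is, to pixel accuracy,
the annulus with inner radius `R·√0.8`.

`detect_nuclei()` finds stained nuclei as connected components of pixels
darker than a luminance threshold (default 150 of 255 — hematoxylin ≈76
and DAB ≈91 under the default palette, eosin background ≈199), filtered to
areas between 20 and 400 px. A nucleus is called Ki67-positive when red
exceeds blue by a margin (default 30) over at least half its pixels.
`score_ki67()` assigns each nucleus to the zone containing its centroid —
matching manual counting practice, and simpler than area-weighted overlap
— and reports per-zone percent positive. A zone with zero nuclei reports
`NA`, flagged undefined, never 0%: silently scoring an empty zone as 0
would bias group means downward. Centroids outside the tumor go to an
explicit reject bin.

## Caliper volumes and cohort statistics

Tumor volume uses the ellipsoid approximation `V = a·b²/2` with `a` the
longest and `b` the shortest caliper diameter (mm). Measurements with
`a < b` are physically impossible orientations, overwhelmingly data-entry
slips; they are swapped with a warning rather than rejected, in both
`tumor_volume()` and `read_cohort_csv()`. Group summaries are mean ± SEM
with the n−1 SD; single-animal cells report `NA` SEM.

Three test families cover the designs these studies use:

- `mann_whitney_exact()` — the U statistic `min(U1, U2)` with midranks;
  for `n1 + n2 ≤ 20` the two-sided p is exact by full enumeration of all
  `C(n1+n2, n1)` group labelings (the count of labelings with U at most
  the observed value over the total), which handles ties without
  approximation; beyond that, a normal approximation with midrank tie
  correction and continuity correction. Exactness matters here: with
  n = 6–7 per arm the normal approximation is visibly off in the tails.
- `welch_t_from_summary()` — `t = (m1−m2)/√(sem1²+sem2²)` with
  Welch–Satterthwaite df, computable from published mean/SEM/n alone; the
  raw-data wrapper `welch_t()` summarizes and delegates, so the two routes
  agree to machine precision. Welch is the default because group SEMs in
  these studies are routinely unequal; the pooled Student form is a flag
  (`pooled = TRUE`), recovering `df = n1+n2−2`.
- `anova_oneway()` — the classical one-way F for three or more arms.

All p-values are two-sided and uncorrected for multiplicity, matching the
reporting conventions of the study designs this package targets.
`growth_report()` compares each arm to control per day with the exact
Mann-Whitney test, flags the first day with p < α (default 0.05), and runs
all pairwise final-day comparisons on volume and weight. Raw small-sample
comparisons use Mann-Whitney; the summary-statistic t is for contrasts
where only printed summaries exist. Both are always available and the test
used is named in every output row.

## Synthetic-data generators

The generators provide inputs with known ground truth. All randomness
derives from one explicit integer seed per generator call, evaluated in a
protected RNG scope (the caller's stream is untouched), and identical
specs give bit-identical output.

**Percolation fractals.** `gen_percolation_mask(b, p, L)` performs
recursive curdling: one retained cell, subdivided b×b per level, each
child kept with probability p. Supercritical (`b²p > 1`) realizations have
box dimension `log(b²p)/log b`, giving an analytic target for the
estimator; subcritical specs are rejected since no dimension exists. An
extinct realization returns the all-background mask rather than silently
re-sampling — reproducibility over convenience; validation harnesses
re-seed past extinctions. With `b = 5, L = 5` and the retention levels
used in validation (p = 0.702 and 0.462, theoretical dimensions 1.78 and
1.52), extinction is vanishingly rare.

**Sections.** `gen_section()` renders a disk tumor (radius ≥ 32 px, with a
32 px background rim that exceeds the segmentation smoothing support) and
selects necrotic pixels by ranking tumor pixels on a potential field —
distance from the centroid for `compact_interior`, minimum distance to
eight blob centers placed at 60–92% of the radius for
`dispersed_peripheral`, both perturbed by smoothed noise for irregular
boundaries — taking exactly `round(f·A)` pixels. The realized fraction is
therefore exact to 1/A, well within the 0.01 guarantee. Viable tissue gets
~12 nuclei per 1000 px² (dark disks, radius 2–3 px); stain colors are
fixed, well-separated constants (hematoxylin ≈ RGB(60,40,120), eosin ≈
(240,180,190), necrosis ≈ (235,220,215), DAB ≈ (130,80,40)) with Gaussian
jitter (SD 3).

**Ki67 fields.** `gen_ki67_field()` dart-throws non-overlapping nuclei
(bounded retries — an unplaceable density errors out), keeps centers
deeper than one nucleus radius from the boundary so every nucleus lies
wholly inside the tumor, draws positivity as an independent Bernoulli at
the rate of the zone containing the center, and returns the image plus the
full ground-truth table.

**Cohorts.** `gen_cohort()` draws a baseline volume (normal, common mean,
SD = SEM·√n — the definitional reconstruction of between-animal SD from a
printed SEM) and a final volume (normal, arm mean, SD = SEM·√n), truncated
positive, then interpolates *linearly in cube-root volume*. The cube-root
(radius) space is the deliberate choice: tumor growth driven by
proliferation at the border advances the radius roughly linearly, and
linear-in-volume or exponential interpolants would put the mid-study
measurements in visibly different places. Each day's volume is converted
to a caliper pair with aspect ratio drawn uniformly from [1.0, 1.6] such
that `a·b²/2` reproduces the volume exactly. The default three-arm design
— control n = 6 starting at 106.9 ± 3.1 mm³ reaching 519.4 ± 62.9 mm³ at
day 22, with treated arms n = 7 reaching 282.0 ± 30.7 and 202.6 ± 18.1
mm³, measured twice weekly, final weights 0.316 ± 0.017, 0.143 ± 0.029 and
0.129 ± 0.018 g — is the study design the package's validation targets.
Per-day caliper noise is exposed (`measurement_cv`) and defaults to 0,
since no per-measurement variance is published for such designs; the
between-animal draws already carry the printed dispersion.

What the generators do *not* emulate: real H&E texture (chromatin,
stroma, staining gradients, folds), color deconvolution of overlapping
stains, non-disk tumor outlines in the section generator, attrition and
non-monotone growth in cohorts. Passing validation on synthetic data
therefore demonstrates correctness of the measurement chain — the
segmentation rule, the counting geometry, the estimators and tests — under
the stated stain model, not segmentation robustness on real slides, where
the thresholds exposed in `pipeline_config()` would need recalibration.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: a
brute-force double-loop box counter, bitmask enumeration of Mann-Whitney
labelings, closed-form annulus geometry, analytic fractal dimensions
(filled plane, line, level-8 Sierpinski triangle at side 256, percolation
theory values), and the generators' ground truth. Stochastic recovery
checks run at sizes chosen to make their tolerances multi-sigma bounds:
20 percolation masks per retention level at side 5⁵ = 3125; 10 sections of
radius 256 for the 37.4% recovery (tolerance 2 points; Dice ≥ 0.90);
200 cohorts for the day-22 mean-recovery rate; 30 Ki67 fields at radius
192 and density 5/1000 px² so the pooled binomial SE of the outer-zone
percentage (~0.8 points) sits well inside the 2-point tolerance.

One design-power fact worth stating: under the default arm calibration
(282.0 ± 30.7 vs 519.4 ± 62.9, n = 7 vs 6), the exact Mann-Whitney at
α = 0.05 separates the arms by the final day in about 84% of simulated
cohorts — the small group sizes cap the power, and the suite asserts a
bound consistent with that simulated rate rather than near-certain
detection.

## Known limitations

- The necrosis rule is a two-feature threshold classifier; it has no
  concept of stain variability, and its guards (`dens_cap`, `lum_floor`)
  are calibrated to the synthetic palette. Real-slide use requires
  recalibration and ideally stain normalization, which is out of scope.
- Box counting uses one grid offset; dimension estimates on small or
  sparse masks carry anchoring variance that offset-averaging would
  reduce.
- The exact Mann-Whitney enumerates up to a combined n of 20 (184,756
  labelings); larger samples get the tie-corrected normal approximation.
- Zones are defined by distance rank; for highly elongated tumors the
  outer zone concentrates along the long sides, which is the intended
  behaviour of the definition but differs from a manually drawn band of
  constant thickness.
- The cohort generator endpoints are exchangeable draws; it does not model
  within-animal serial correlation beyond the deterministic radius
  interpolation, nor dropout.
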