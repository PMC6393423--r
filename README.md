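# xenometry

Tumor morphometry and cohort statistics for subcutaneous xenograft studies.

Preclinical xenograft experiments quantify treatment effect through a small
set of recurring endpoints: caliper-derived tumor-volume growth curves, the
percentage of the tumor cross-section that is necrotic on H&E-stained
slides, the spatial pattern of that necrosis, and the distribution of
proliferating (Ki67-positive) cells across the tumor depth. `xenometry`
implements this whole measurement chain for R users — image analysts and
biostatisticians working on small-animal oncology studies — together with
seeded synthetic-data generators that provide ground truth for validating
every stage.

## What it computes

- **Percent intratumoral necrosis** — `segment_necrosis()` classifies tumor
  pixels from two smoothed feature maps (nuclear density and pallor,
  Otsu-thresholded with absolute guards) and `percent_necrosis()` reports
  `100·|necrosis| / |tumor|` from exact pixel counts.
- **Box-counting fractal dimension** `d_f` of a binary pattern —
  `box_count()` counts occupied `ε×ε` grid cells over a geometric scale
  ladder and `fractal_dimension()` fits `ln N(ε) = -d_f·ln ε + c` by
  ordinary least squares. A filled region gives `d_f ≈ 2`, a curve
  `d_f ≈ 1`; dispersed necrotic patterns sit in between.
- **Concentric 20/30/50% zonal partition** — `partition_zones()` ranks
  tumor pixels by Euclidean distance to the tumor boundary and cuts the
  ranking at 20% and 30% of the area, yielding outer / intermediate /
  inner zones that are exact to one pixel for any tumor shape;
  `detect_nuclei()` + `score_ki67()` report the per-zone percentage of
  Ki67-positive (DAB-brown) nuclei.
- **Growth curves and tests** — `tumor_volume()` applies the ellipsoid
  caliper formula `V = a·b²/2` (a = longest, b = shortest diameter),
  `summarize_cohort()` gives per-group-day mean ± SEM, and
  `growth_report()` runs exact Mann-Whitney U comparisons against control
  per day, flagging the first day of separation. `mann_whitney_exact()`
  (full enumeration with midranks), `welch_t_from_summary()` (Welch t from
  published mean/SEM/n), `welch_t()` and `anova_oneway()` are exported
  directly.
- **Synthetic ground truth** — `gen_percolation_mask()` (Mandelbrot
  percolation with known dimension `log(b²p)/log b`), `gen_section()`
  (H&E-like sections with an exact necrotic fraction, compact-interior or
  dispersed-peripheral), `gen_ki67_field()` (non-overlapping nuclei with
  zone-dependent positivity), and `gen_cohort()` (multi-arm caliper tables
  interpolated linearly in cube-root volume between calibrated baseline and
  final distributions).

## Worked example

```r
library(xenometry)

sec <- gen_section(256, 0.374, "compact_interior", seed = 1)
(seg <- segment_necrosis(sec))
#> <necrosis_result> 38.02% of 205861 tumor px necrotic

fractal_dimension(seg$necrosis_mask)
#> <fractal_fit> d_f = 1.8519 (SE 0.0199, R^2 0.9994) over 7 scales [2..128]

partition_zones(sec$tumor_mask)
#> <zone_partition> outer/intermediate/inner = 20.0/30.0/50.0% of 205861 tumor px

welch_t_from_summary(37.4, 4.6, 7, 7.5, 3.0, 7)
#> <welch_t_from_summary> statistic = 5.44447, p = 0.000253289, df = 10.32

ct <- gen_cohort(seed = 1)   # three-arm study design, days 0..22
growth_report(ct, control = "control")$first_signif
#>       group first_day_p_below_alpha
#>      rhGCSF                       4
#> gemcitabine                       4
```

The section was generated with a true necrotic fraction of 37.4%; the
segmentation recovers 38.0%. The compact necrotic blob is nearly
space-filling, hence `d_f` close to 2. The summary-statistic Welch test
shows the 37.4 ± 4.6% vs 7.5 ± 3.0% necrosis contrast (n = 7 per arm) is
significant at p < 0.001. In the simulated cohort, both treated arms
separate from control by day 4 by exact Mann-Whitney test.

An end-to-end run (simulation → necrosis → fractal → zones → Ki67 → growth
statistics, with CSVs, PNGs, a growth-curve figure and a run log under one
directory) is:

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
```

and a thin command-line wrapper with per-stage subcommands is installed at
`inst/cli/xenometry.R`.

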