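Package: xenometry
Title: Tumor Morphometry and Growth Statistics for Xenograft Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative morphometry and cohort statistics for subcutaneous
    xenograft tumor studies. Provides seeded generators for synthetic
    histology-like section images, Mandelbrot percolation fractals of known
    box dimension, Ki67-stained nucleus fields and longitudinal caliper
    cohorts; necrosis segmentation and percent-necrosis quantification on
    stained sections; box-counting fractal dimension estimation of binary
    necrotic patterns; concentric 20/30/50 percent zonal partitioning by
    distance-to-boundary rank with per-zone Ki67 positivity scoring; and
    caliper growth-curve summaries with exact Mann-Whitney, Welch t
    (including the summary-statistic variant) and one-way ANOVA tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
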