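Package: telonoise
Title: Simulation and Analysis of Telomere-Adjacent Gene Expression Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying expression noise at telomere-adjacent
    genes. Provides a two-state (telegraph) chromatin-toggling simulator for
    per-cell fluorescence, colony founder effects, mother-daughter pedigrees,
    flow-cytometry event streams, multi-condition expression matrices and
    rendered nuclear image stacks; variability statistics (coefficient of
    variation, quantile-based Robust CV, delta-CT abundance, variance-ratio
    tests); dual-reporter decomposition of cell-to-cell noise into intrinsic
    and extrinsic components; bootstrap gene-set and CV-ratio tests and a
    mother-daughter permutation test of expression heritability; telomere-rank
    positional scans of transcriptional variability; and region-based nuclear
    fluorescence quantification with background subtraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
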