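Package: vesiclequant
Title: Quantification of pHluorin Synaptic Vesicle Exocytosis Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pHluorin-based optical measurements of
    synaptic vesicle exocytosis in cultured neurons. Converts raw region-of-
    interest (ROI) fluorescence time series into photobleach-corrected,
    baseline-normalized dF/F0 traces; screens ROIs and fields of view with
    strict inclusion criteria; extracts recycling-pool size, one-phase
    exocytosis time constants, initial exocytic rates and readily releasable
    pool estimates; quantifies protein localization (coefficient of variation
    along axons, surface/vesicle membrane partitioning, expression
    fold-change); performs normality-gated group comparisons against a
    wild-type control; and tests genotype-function-phenotype associations via
    permutation-based Spearman correlation with Benjamini-Hochberg false
    discovery rate control. A synthetic-data generator produces complete
    in-silico experiments with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    multcomp,
    car,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
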