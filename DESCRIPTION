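Package: seroscreen
Title: Seroreactivity Profiling and Autoantibody Biomarker Panel Discovery
    for Protein Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering diagnostic autoantibody biomarkers from
    antigen microarray serology data. Provides spot-level ingestion with
    background subtraction and replicate collapse, reference-serum quality
    control, intra-array median and inter-array quantile normalisation,
    interquartile-range seroreactivity cutoffs with signal-to-cutoff ratios,
    per-antigen biomarker scores and per-sample serum scores, a two-stage
    panel selector combining repeated random-forest importance rank
    aggregation with a classification tree, diagnostic ROC evaluation, and a
    synthetic-cohort generator with planted seroreactive antigens so that
    every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    limma,
    ranger,
    rpart,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
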