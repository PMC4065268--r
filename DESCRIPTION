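Package: antherprog
Title: Expression Progression Analysis for Staged Maize Anthers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-color microarray experiments profiling an
    ordered developmental series of maize anthers. Implements present/absent
    detection calling from negative-control statistics with an analytic false
    detection rate, within-array loess and between-array quantile
    normalization, classification of stage-expression patterns (constitutive,
    stage-specific, trough), differential expression with fold-change and
    p-value rules, sequential marker-gene filters (pluripotency decline,
    mutant persistence, direct-target overlap), laser-capture-microdissection
    cell-type enrichment and non-lobe tissue assignment, transcript-protein
    abundance concordance with decile binning, and a synthetic-data generator
    that plants recoverable expression patterns emulating the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
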