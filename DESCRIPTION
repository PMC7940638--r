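Package: genomicDUS
Title: Genomic Evaluation of the DUS Plant Variety Registration System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for evaluating plant variety registration under the
    Distinctness, Uniformity and Stability (DUS) framework with genome-wide
    markers, using inbred barley as the model system. Implements genomic
    relationship matrices and restricted maximum likelihood (REML)
    estimation of narrow-sense heritability and genetic correlations for
    ordinal DUS traits, mixed-linear-model genome-wide association scans
    with Storey q-value FDR control and conditional re-scans, simulation of
    meiosis and inbred crossing schemes (F6, BC1S4) over a genetic map, and
    a distance-based "genomic DUS" decision framework covering
    distinctness, essentially-derived-variety screening, seed-lot
    uniformity and stability. A synthetic-panel generator reproduces the
    statistical structure of a two-season (spring/winter) inbred variety
    collection so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
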