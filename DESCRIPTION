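Package: genedose
Title: Gene Dosage and Expression Scoring for Dual-Probe FISH, qPCR and IHC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and classification procedures for assessing gene
    dosage and expression across tumor subtypes: dual-probe FISH copy-number
    interpretation (amplification versus chromosome polysomy), delta-delta-Ct
    relative expression with banded calls, the ImmunoReactive Score (IRS) for
    immunohistochemistry, a region peak-area statistic on genomic signal
    tracks, and copy-number/expression correlation and subtype comparison.
    Includes synthetic-data generators with the statistical structure each
    stage assumes, so every stage is testable without access to raw tumor or
    cell-line data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
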