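Package: hypoxigen
Title: Genomic and Transcriptomic Instability Analysis Under Chronic Hypoxia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying how long-term hypoxia reshapes
    the genome and transcriptome of cancer cell lines. Implements signature
    based hypoxia scoring and hypoxia-high/hypoxia-low stratification of cell
    lines and patient cohorts, paired hypoxia-minus-normoxia variant
    normalization from MAF tables with tumor mutational burden and variant
    spectrum summaries, windowed read-depth copy-number calling with ploidy
    selection, moderated differential-expression and splicing-index
    thresholding, and the group statistics (t-based confidence intervals,
    unpaired t-tests, one-way ANOVA with Sidak correction) used to compare
    the two hypoxia groups. A synthetic-data module generates every input
    with the statistical structure the analysis assumes, so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
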