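Package: riskomics
Title: Integrated Transcriptome-Methylome Identification of Risk Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates genome-wide expression and DNA methylation profiles
    from a three-group cohort design (controls, unaffected high-risk
    individuals, patients) to identify "risk genes": features altered in both
    control-referenced contrasts. Implements quantile normalisation and
    per-gene Student's t differential expression with Benjamini-Hochberg
    control, delta-beta differential methylation calling on Infinium-style
    beta values, cross-contrast concordance, expression-methylation Pearson
    correlation integration, and right-tailed hypergeometric gene-set
    enrichment with universe inference from singleton-pathway p-values. A
    seeded synthetic matched-omics cohort generator with planted effects
    supports end-to-end recovery testing without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'concord.R'
    'correlate.R'
    'diffexpr.R'
    'diffmeth.R'
    'enrich.R'
    'io.R'
    'pipeline.R'
    'riskomics-package.R'
    'simulate.R'
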