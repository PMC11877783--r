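Package: clonalProvenance
Title: Clonal Provenance of Recurrent Tumors from Longitudinal Matched Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies the clonal origin of recurrent tumors from deep
    panel sequencing of matched blood, subventricular-zone (SVZ), primary
    and recurrent specimens. Provides detection-limit-aware presence
    calling per tissue, mutation-sharing categorization (SVZ-Tumor-shared,
    Inter-Tumor-shared, Primary-private, Recurrent-private, SVZ-private),
    rule-based patient-level recurrence-pattern classification
    (SVZ-associated, Primary-associated, Unknown), and simplified
    VAF-constraint lineage-tree reconstruction. A branched clonal-evolution
    simulator generates matched four-sample datasets with ground truth so
    every stage can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'categorize.R'
    'classify.R'
    'cohort-fixture.R'
    'lineage.R'
    'pipeline.R'
    'presence.R'
    'sim-clonal.R'
    'utils.R'
    'variant-io.R'
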