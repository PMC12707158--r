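Package: rankdx
Title: Phenotype-Specific Gene Rank-Annotation Scores and Clinical Exome
    Diagnostic Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing candidate disease genes and auditing
    clinical exome sequencing (cES) cohorts. Scores every gene in a genome
    against a phenotype-specific training gene set across multiple
    annotation knowledge sources, combines the per-source similarities into
    omnibus percentile rank-annotation scores (0-100%), and validates the
    ranking by leave-one-out cross-validation with ROC-style curves and the
    area under the curve above the diagonal. Bins reported variant findings
    into definitive, probable and provisional diagnoses with a configurable
    rule table that includes compound-heterozygous (in trans) rules for
    autosomal recessive conditions, computes cohort diagnostic efficacy and
    commercial gene-panel coverage, and applies a rule-based evidence
    integrator for phenotypic-expansion candidate genes. A synthetic-data
    module generates knowledge sources with planted disease-gene signal and
    cohorts with exact diagnostic-certainty composition so the full pipeline
    runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
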