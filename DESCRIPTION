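Package: osteoevo
Title: Longitudinal Tumor Evolution Analytics for Osteosarcoma Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for longitudinal (primary plus recurrence)
    tumor genome cohorts, built around the questions that arise in
    metastatic osteosarcoma: hard-filtering and in-silico prioritization of
    annotated somatic variants; maximum-parsimony sample phylogenies rooted
    at the matched normal, with homoplasy index, bootstrap supports, and
    trunk/branch/leaf variant assignment; allele-specific copy-number
    analytics including homologous-recombination-deficiency (HRD) genomic
    scar scores (LOH, TAI, LST) with composite classification,
    chromothripsis and staircase-amplification detection; 96-channel
    mutational-signature exposure fitting by expectation-maximization with
    molecular-clock back-dating of tumor origin and metastatic divergence;
    margin-constrained mutual-exclusivity testing of driver alterations;
    and a genomics-guided CDK/PARP therapy decision tree. A synthetic-cohort
    generator with full ground truth makes every stage testable without
    access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    pracma,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
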