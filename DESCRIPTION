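Package: tumoronly
Title: Tumor-Only Somatic Mutation Filtering and Prognostic Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Somatic mutation analysis for targeted-capture tumor sequencing
    without matched normal DNA, as used for archival estrogen-receptor-positive
    breast cancer cohorts. Implements a multi-stage tumor-only filtering cascade
    (population allele frequencies, unmatched-normal call counts, read-count
    panels of normals, a binomial log-likelihood-ratio somatic classifier, and
    knowledge-base hotspot rescue), recurrence and amino-acid-level hotspot
    enrichment testing against a multi-study reference catalog,
    mutation-covariate association testing with false-discovery-rate control,
    and gated Kaplan-Meier / Cox survival screening with year-5 episode
    splitting and min-p permutation family-wise adjustment. A synthetic cohort
    generator produces fully labeled variant, clinical, survival and
    reference-panel data with the statistical structure the analysis assumes,
    so the entire pipeline is testable without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
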