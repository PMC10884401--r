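Package: sirenet
Title: Paternal Drug-Seeking Motivation and Offspring Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking paternal operant drug-seeking motivation to
    offspring brain transcriptome structure. Implements composite motivation
    scoring of self-administration session logs with top-fraction sire
    selection, negative-binomial Wald differential expression with
    median-of-ratios normalization, weighted gene co-expression network
    construction (soft thresholding, topological overlap, module detection,
    eigengenes, intramodular connectivity), module and gene-set
    overrepresentation statistics, cross-state sign-consistency profiling,
    and hub-gene screening by joint connectivity and phenotype correlation.
    Includes a negative-binomial synthetic-data generator with planted
    modules, differential genes and a motivation-coupled hub module, so the
    whole inference chain can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
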