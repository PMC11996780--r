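Package: vetaemine
Title: Mining Veterinary Electronic Health Records for Adverse Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies drug-adverse-event pairs in free-text veterinary
    electronic health records. Seed adverse-event dictionaries are expanded
    with corpus-specific skip-gram word embeddings (synonyms, misspellings,
    abbreviations), compiled into context-aware pattern matchers with
    negative look-around exceptions, and applied to clinical narratives.
    Exposure cohorts are built from treatment records through a staged
    exclusion cascade (missing narratives, no post-exposure data,
    pre-existing signs, product crossover), follow-up windows are derived
    from time-to-onset statistics or drug half-life, and incidence per
    10,000 animals, Katz relative risk and Mantel-Haenszel age-adjusted
    relative risk are computed. A synthetic EHR generator with planted
    ground truth makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
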