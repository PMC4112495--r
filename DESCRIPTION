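Package: cbdcriteria
Title: Rule Engine and Cohort Statistics for the Armstrong Corticobasal
    Degeneration Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies longitudinal clinical-feature records into the five
    Armstrong clinical phenotypes of corticobasal syndrome (probable and
    possible CBS, frontal behavioural-spatial syndrome, the non-fluent/
    agrammatic variant of primary progressive aphasia, and the progressive
    supranuclear palsy syndrome) and into probable/possible corticobasal
    degeneration (CBD) diagnoses with the published exclusion criteria.
    Provides the accompanying clinicopathological validation statistics:
    documented-denominator feature frequencies, correlation of frequency
    profiles against the published reference, 2x2 group comparisons
    (Pearson, Yates and Fisher), diagnostic sensitivity and specificity
    against neuropathology, and nested classification summaries. Includes a
    seeded synthetic-cohort generator emulating a two-group
    clinicopathological series (CBD pathology vs CBD mimics) with
    documentation missingness, so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
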