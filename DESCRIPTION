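Package: crohnsim
Title: Patient-Level Simulation of Crohn's Disease Surveillance with Capsule Endoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-event, patient-level microsimulation of Crohn's disease
    surveillance comparing video capsule endoscopy against standard of care
    (ileocolonoscopy with or without magnetic resonance enteroscopy). Disease
    activity evolves through a semi-Markov process with monthly CDAI-band
    transitions nested in 3-month model cycles; a configurable care pathway
    applies fecal-calprotectin gating, imperfect diagnostic tests, treatment
    escalation and surgery routing, and prices every billable event into four
    cost buckets for budget-impact reporting. Includes a synthetic baseline
    cohort generator, multivariate bootstrap and one-way cost sensitivity
    analyses, clinical-outcome extraction under permissive and restrictive
    definitions, cumulative-incidence series on a semiannual grid, and a
    Beta-posterior model-acceptance statistic for external validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
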