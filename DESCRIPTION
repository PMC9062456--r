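Package: hmisdisrupt
Title: Quantifying Health Service Disruption from Routine District HMIS Data
Version: 0.1.0
Authors@R: person("Countdown", "Analytics", email = "analytics@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the continuity of essential health services
    from district-level routine health information system (DHIS2-style)
    monthly counts. Provides data-quality assessment (facility reporting
    completeness, missing values, modified Z-score outlier detection),
    curation (completeness adjustment, calendar-year median imputation,
    exclusion windows), bottom-up aggregation to national / region /
    urban-rural strata, mixed-effects interrupted-period estimation of
    COVID-period percent changes in service utilisation with 95% confidence
    intervals, and pooled association of monthly changes with the Oxford
    government-response stringency index. Includes a synthetic HMIS
    scenario generator with known ground truth so the full pipeline is
    testable without access to country extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
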