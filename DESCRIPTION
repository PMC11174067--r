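Package: fibertol
Title: Gastrointestinal Tolerance Scoring and Microbiome Association
    Analysis for Dietary-Fiber Trials
Version: 0.1.0
Authors@R:
    person("Fibertol", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify gastrointestinal symptom severity and
    adaptation from weekly ordinal symptom diaries collected in dietary
    fiber supplementation trials, and to relate individual tolerance to
    fecal microbiota composition, metabolically active taxa, fecal pH and
    short-chain fatty acid shifts, and habitual diet.  Implements MAX and
    area-under-the-curve severity and adaptation scores, taxonomic and
    co-abundance-group feature engineering with mean-abundance filtering,
    rank-based association testing with exact small-sample options, and a
    fully seeded synthetic cohort generator that emulates a two-arm
    randomized controlled fiber trial for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
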