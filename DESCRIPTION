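Package: msdrisk
Title: Musculoskeletal-Disorder Health-Risk Assessment from Self-Report and RULA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screening pipeline for work-related musculoskeletal disorder
    (MSD) risk. Scores per-region self-reported pain (frequency x severity
    ranks, 0-16) into five discomfort levels, computes Rapid Upper Limb
    Assessment (RULA) grand scores from posture codes via the standard
    worksheet lookup tables, combines the two in a 5 x 4 health-risk matrix
    with a five-level classification per body region, and summarises cohorts
    as per-level count/percentage prevalence tables. Includes a synthetic
    cohort generator with controllable categorical marginals and a
    Gaussian-copula association between discomfort and posture risk, plus
    CSV input/output and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
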