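Package: flycourt
Title: Courtship-Based Behavioral Phenotyping for Parkinson's Model Drosophila
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies male Drosophila courtship from annotated bout-level event
    logs and scores Parkinson's-model (alpha-synuclein A30P) flies against
    wild-type controls. Computes per-couple courtship parameters (orientation and
    wing-vibration time, licking, attempted copulations, copulation, non-sexual
    encounters and the sexual focus index SFI = 1/(NSE + 1)), time-normalized
    group summaries, relative-activity percentages and a six-trait composite
    courtship score; scores the negative-geotaxis climbing assay; and provides an
    association-rule learner that discovers interval "if then" rules over the
    eight per-fly features and assembles a necessary-and-sufficient ("if and only
    if") rule set for diagnosing health condition, with success rate and
    improvement factor. A synthetic-data generator reproduces the study design
    (two genotype groups, 600 s observations, copulation-truncated sessions) so
    the full pipeline is testable without the unpublished recordings.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
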