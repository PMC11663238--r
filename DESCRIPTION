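Package: anatscore
Title: Anatomical Error Scoring and Agreement Analysis for AI-Generated Human Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tooling for a structured human-annotation rubric that classifies
    anatomical errors in AI-generated photorealistic images of people. Errors
    are recorded per anatomical region (face, torso, hands, limbs, feet), error
    type (proportion, extra, orientation, configuration, missing) and severity
    (a/b/c), and aggregated into a proportion-of-errors statistic and a
    severity-weighted cumulative score per image. The package provides
    validated CSV/JSON annotation input and output, quantile-based overall
    severity levels per annotator, Krippendorff's alpha (nominal, ordinal and
    interval) for pairwise inter-rater agreement on three metric variants,
    Welch two-sample comparisons between generator models and prompts,
    seeded constrained randomisation of annotation assignments with a
    double-annotation fraction, and a synthetic annotation generator for
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
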