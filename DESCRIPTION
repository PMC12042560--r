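Package: qmoaks
Title: Quantitative MOAKS-Style Cartilage Morphometry Scoring
Version: 0.1.0
Authors@R: person("OA Morphometry", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for quantitative, landmark-based knee cartilage morphometry
    on the 10 tibiofemoral MOAKS subregions. Builds a per-landmark normative
    thickness model from a non-OA control cohort, classifies cartilage
    thinning (< 95% of normative) and denudation (< 5% of normative) at each
    corresponded bone-surface landmark, aggregates these into per-subregion
    area percentages (ThQCM%, dQCM%) and ordinal 0-3 scores banded exactly
    like MOAKS, and computes regional mean cartilage thickness (ThCtAB).
    Includes concordance statistics (cross-tabulation, tie-corrected Spearman
    correlation with Fisher-z confidence intervals), longitudinal
    responsiveness (standardised response means with percentile-bootstrap
    confidence intervals), and a synthetic cohort generator that emulates a
    non-OA control population and a radiographically progressing cohort with
    focal, growing cartilage lesions plus an optional simulated
    semi-quantitative reader.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
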