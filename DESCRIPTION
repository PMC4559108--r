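Package: urostab
Title: Stability Screening of the Human Urine Metabolome Under Collection Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for LC-MS metabolomics studies of human-urine
    stability during sample collection. Provides quality-control-based loess
    correction of injection-order signal drift, blank and repeatability
    filtering, accurate-mass/retention-time annotation against a spectral
    library, per-condition Spearman screening of intensity versus storage
    duration with Benjamini-Hochberg false-discovery-rate control, PCA and
    two-component PLS modelling with cross-validated Q2, permutation testing
    and VIP ranking, and classification of unstable metabolites as affected
    by bacterial overgrowth or by chemical instability. A synthetic-data
    generator emulates the study design (two experiments, storage at room
    temperature, at 4 degrees C or with preservative, 0-72 h time courses,
    triplicates, interleaved QC and blank injections, two ionisation modes)
    with planted drift and planted unstable metabolites so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    jsonlite
Config/testthat/edition: 3
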