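Package: growrisk
Title: Presence-Background Maximum-Entropy Risk Mapping for Trespass
    Cannabis Cultivation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the landscape-scale distribution of trespass cannabis
    cultivation sites from presence-only locality data using an
    L1-regularized maximum-entropy (Gibbs) model with linear, quadratic,
    product and hinge features.  Implements the full risk-mapping
    pipeline: spatial thinning of occurrences, background sampling,
    focal-window predictor smoothing, correlation-based variable
    grouping with univariate AUC selection, stepwise jackknife variable
    reduction, feature-type by regularization tuning by AICc,
    continuous Boyce-index classification into low/moderate/high risk,
    stream-survey ground-truth statistics, and overlap of risk classes
    with habitat layers and adaptive local convex hull (a-LoCoH) home
    ranges.  Includes a synthetic-landscape generator so the pipeline
    can be exercised end-to-end without proprietary GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite, yaml, sp, EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
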