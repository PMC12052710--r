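Package: rumenMWAS
Title: Marker-Based Fiber Degradation Rates and Two-Part Microbiome-Wide
    Association Analysis for Rumen Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links ruminal fiber degradation rates to feed efficiency and
    rumen microbiota composition. Computes neutral and acid detergent fiber
    degradation rates from acid-insoluble ash internal-marker concentrations,
    growth and feed-conversion metrics, depth normalization and centered
    log-ratio transforms of genus-level abundance tables, extreme-phenotype
    group construction with outlier trimming, Spearman rank-correlation
    screening, a prevalence-routed two-part microbiome-wide association model
    with principal-component adjustment and permutation p-values, high-vs-low
    group differential abundance testing, and a three-method consensus with
    phylum tallies. Includes a synthetic cohort generator with planted causal
    genera for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
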