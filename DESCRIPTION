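Package: photoniche
Title: Photic-Niche Analysis for Depth-Segregated Reef Corals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the light-driven depth zonation of symbiotic
    reef corals. Estimates the diffuse attenuation coefficient (Kd) from
    underwater light profiles, computes the maximum excitation pressure over
    photosystem II (Qm) from pulse-amplitude-modulated (PAM) chlorophyll
    fluorescence yields, fits per-species linear Qm-depth models and
    extrapolates each species' theoretical depth limit with bootstrap
    confidence intervals, and analyses reciprocal-transplant survivorship with
    one-tailed Fisher exact tests and standardized selection differentials.
    Includes a synthetic-data generator that emulates field light profiles,
    temperature/light logger series, PAM fluorometry surveys and transplant
    outcomes, so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
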