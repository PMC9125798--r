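Package: baleenT
Title: Annual Testosterone Cycle Analysis Along Baleen Plates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and characterises annual testosterone (T) cycles in
    longitudinal hormone profiles drilled at uniform 2-cm spacing along
    baleen plates of mysticete whales. Provides Gaussian low-pass
    detrending, autoregressive spectral estimation of cycle period with
    AIC order selection, cross-correlation phase offsets between T and
    stable-nitrogen-isotope cycles, peak detection and cycle segmentation
    with baseline and peak/baseline metrics, per-cycle age assignment,
    von Bertalanffy length-based age estimation, linear mixed-effects
    trend models of peak T and cycle period against age with AICc
    selection, and a seeded synthetic-profile generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
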