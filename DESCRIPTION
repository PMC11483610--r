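Package: isopbpk
Title: Bottom-Up PBPK Models for Genistein and Daidzein with a Dermal Module
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body physiologically based pharmacokinetic (PBPK) models for the
    isoflavones genistein and daidzein, built bottom-up from in vitro ADME inputs.
    Includes Rodgers-Rowland tissue partitioning, well-stirred hepatic IVIVE, a rat
    oral model with Weibull dissolution, a human dermal route with a finite-difference
    multilayer skin-permeation module including cutaneous first-pass metabolism,
    virtual-population simulation, local sensitivity analysis, and reverse dosimetry
    from in vitro points of departure to external doses for use in next-generation
    risk assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
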