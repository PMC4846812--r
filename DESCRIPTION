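Package: batwake
Title: Wake Reconstruction and Vorticity-Based Weight-Support Estimation for Flapping-Flight PIV
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-resolved transverse-plane particle image
    velocimetry (PIV) measurements of animal wakes, developed around the wake of
    slow-flying bats. Provides per-frame vector validation and repair, pseudo-3D
    wake reconstruction under the Taylor frozen-flow hypothesis, Q-criterion
    vortex identification and segmentation, and momentary and wingbeat-averaged
    weight support from the spanwise first moment of streamwise vorticity. A
    synthetic vortex-filament wake generator (regularised Biot-Savart with
    Lamb-Oseen cores) with analytically known impulse makes every stage testable
    end to end without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
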