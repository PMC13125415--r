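Package: flashbp
Title: Single-Energy Bragg-Peak Proton FLASH Planning with Brass Apertures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Tools for planning and evaluating single-energy Bragg-peak (SEBP)
    proton FLASH fields collimated by thick brass apertures. Provides beamline
    device design (universal range shifter, ray-traced range compensator,
    aperture with margin), an analytic Fermi-Eyges pencil-beam dose engine with
    a thick-aperture phase-space transmission model, minimum-MU spot-weight
    optimization, spot-timing and average-dose-rate (ADR) computation, and a
    metric suite (80-20 penumbra, DVH, DRVH, V40Gy/s, conformity index).
    Includes scripted experiments: a 108-cell water-phantom penumbra sweep over
    field size, range pullback, and air gap, and a synthetic head-phantom
    three-field FLASH plan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
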