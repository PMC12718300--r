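Package: airdisp
Title: Decomposition of Air-Pollution Exposure Disparities and Emission-Reduction Scenario Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying demographic disparities in air-pollution
    exposure. Absolute exposure disparity for a population subgroup is
    decomposed as the product of three controllable components: total
    emissions, the population-average exposure factor (exposure per unit
    emission, an intake-fraction analogue), and the relative disparity in
    exposure. Includes a deterministic illustrative model of a segregated
    city (a radially decaying population on a square grid with a west-east
    demographic gradient, and a two-dimensional Gaussian concentration field
    from a point source, optionally with first-order decay), an engine for
    emission-reduction policy scenarios that relocate the source while
    emissions decline linearly, component-change reporting, and CSV/YAML
    input-output with a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
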