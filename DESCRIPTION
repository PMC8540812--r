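Package: trapdensity
Title: Absolute Insect Population Density from Single Trap Catches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the most probable absolute insect population density
    and its exact statistical bounds from a single trap catch. Implements a
    universal catch-probability-versus-distance model for insect trap
    systems, a two-step nonlinear least-squares protocol that estimates the
    model parameters spTfer(0) and D50 from release-recapture experiments,
    the catch-to-density conversion constant mu, and exact chi-square
    (Garwood-type) confidence bounds for the density given an observed
    Poisson trap count. Includes a binomial/Poisson simulator for
    release-recapture designs and trap catches, bundled parameter presets
    for ten published trap-insect systems, CSV input/output and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
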