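Package: perimotion
Title: Shear-Stress Dosimetry of Neuroelectrode Micromotion
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduced-order biofluid mechanics of the peri-electrode void
    around chronically implanted neural probes. Computes the oscillatory
    wall shear stress (WSS) that electrode micromotion imparts to brain
    tissue across a fluid-filled gap (quasi-steady zero-net-flux Couette
    model, an unsteady finite-difference Stokes solver, and an optional
    tip squeeze-film term), calibrates parallel-plate flow-chamber (PPFC)
    flow rates that deliver matched WSS in vitro, simulates expansion of
    the peri-electrode void to a steady state set by a WSS threshold, and
    generates seeded synthetic micromotion and noisy WSS traces with
    single-parameter recovery of gap or viscosity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
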