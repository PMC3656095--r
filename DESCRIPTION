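Package: reinworld
Title: Rein-Control Homeostasis in Coupled Biota-Environment Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for Daisyworld-class models of
    emergent environmental homeostasis. Biotic components with bounded niche
    functions exert fixed random effects on shared environmental variables;
    the coupled ordinary differential equations self-organise into
    rein-control feedback states. The package integrates the dynamics under
    ramp and shock forcing, represents the large-diversity limit of the
    total biotic force as a stationary Gaussian random field sampled on a
    grid, and provides a census of the emergent stable states: zero-crossing
    counts with a Rice-formula oracle, Kac-Rice expected counts and their
    scaling with the number of environmental variables, diversity thresholds
    for saturation, basin-of-attraction maps, essential-range survival
    probabilities, and hysteresis loops under quasi-static forcing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
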