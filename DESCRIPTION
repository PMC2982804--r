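Package: mtlength
Title: Microtubule-Driven Cell Length Homeostasis: Simulation and Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic half-cell model of cell elongation driven by a fixed
    pool of dynamic microtubules that nucleate at the cell centre, undergo
    cortex-induced catastrophe, and cooperatively advance the cell boundary.
    Provides steady-state and homeostasis analyses (parameter sweeps,
    perturbation protocols, microtubule density profiles, length versus
    growth-velocity regression), closed-form mean-field approximations used
    as independent checks of the simulator, a ground-truthed synthetic
    microscopy generator for micropatterned cells and plus-end comet tracks,
    and the corresponding image-measurement procedures (pattern width, cell
    length, filament orientation distributions, contact-fate classification,
    intensity-based filament counting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
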