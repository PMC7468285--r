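Package: omam
Title: Operational Model of Allosterically-Modulated Agonism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward response functions, derived potency and efficacy
    relations and a staged fitting workflow for the operational model of
    agonism and its extension to allosteric modulators and allosteric
    agonists.  Includes closed-form apparent EC50/Emax and dose-ratio
    expressions, radioligand-binding models (saturation, two-site
    competition, allosteric tracer shift) used to predetermine binding
    constants, a nonlinear least-squares engine with fixed/free parameters
    for global curve fitting, and a synthetic-data generator with presets
    covering the canonical modulation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
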