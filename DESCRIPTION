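Package: mcloop
Title: Digital Twin of a Biventricular Mock Circulatory Loop Under VA-ECMO
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped-parameter (0D) simulator of a biventricular mock
    circulatory loop: time-varying elastance ventricles with switchable
    interventricular coupling, a per-beat Frank-Starling controller,
    gas-column Windkessel compliance chambers, upper/lower-body systemic
    branches, and a veno-arterial ECMO circuit with a centrifugal pump and
    selectable antegrade or retrograde arterial return.  Ships calibrated
    presets for normal, left-, right- and biventricular-failure states, an
    experiment harness (right-atrial clamp tests, Frank-Starling validation,
    pump-speed, aortic-pressure and contractility sweeps, return-direction
    comparison) and the associated regression and ANOVA summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
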