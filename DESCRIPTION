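Package: shuntsim
Title: Lumped-Parameter Simulation of Intracardiac Shunt Hemodynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-loop zero-dimensional (lumped-parameter) model of the
    human circulation with configurable atrial and ventricular septal-defect
    branches. Cardiac chambers are time-varying elastance pressure
    generators, the systemic and pulmonary circulations are arterial and
    venous Windkessel (RLC) compartments, and heart valves are
    pressure-gated resistors. The package integrates the stiff 12-state
    system to its periodic steady state with a compiled right-hand side,
    computes cycle-averaged hemodynamics (pulmonary-to-systemic flow ratio
    Qp/Qs, shunt flows, vascular resistances in Wood units), and provides a
    sweep engine to study how Qp/Qs responds to pulmonary vascular
    resistance, right-ventricular passive elastance, relaxation time and
    defect size in pre- versus post-tricuspid shunts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    pracma,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
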