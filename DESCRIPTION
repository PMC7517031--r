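Package: birhythm
Title: Birhythmic Oscillator Simulation and Closed-Loop Neurostimulation Testbed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a three-dimensional continuous-time gated recurrent unit
    (ct-GRU) dynamical system exhibiting birhythmicity: two stable limit cycles
    of different periods, mirrored across the invariant z = 0 plane. Provides a
    state-dependent nonlinear stimulator interface (S_out = S_in * x * y),
    baseline open-loop stimulation protocols (constant, random telegraph,
    periodic, diode-gated), a reset/step control environment for closed-loop
    algorithms, attractor characterization tools (fixed points, Poincare-section
    period estimation, basin classification, trial batteries), and an analog
    hardware emulation layer (op-amp/transistor tanh unit, component-tolerance
    perturbation). Intended as a software testbed for stimulation strategies
    that must induce transitions between basins of attraction through a
    nonlinear interface that defeats open-loop stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
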