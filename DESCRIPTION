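Package: perfusim
Title: Digital Twin of a Pressure-Driven Recirculating Perfusion System
    for Organ-on-Chip Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lumped-element hydraulic modelling and closed-loop simulation
    of pressure-driven perfusion for multiplexed organ-on-chip devices.
    Provides Hagen-Poiseuille resistance formulas for rectangular channels
    and circular tubing, a nodal network solver with passive check valves
    (including the four-valve Graetz rectifier used for passive
    recirculation), a time-domain plant model of paired medium reservoirs
    with evolving pressure head and asymmetric pneumatic dynamics, sensor
    models (thermal flow-sensor fouling and saturation, dampened paired
    gauge pressure sensors, hydrostatic liquid-level sensing), and a PID
    pressure-difference controller with level-triggered recirculation
    switching. Includes fixture circuits, a fluidic-circuit-board builder
    with blockage analysis, JSON circuit/config I/O and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
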