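Package: tbadflow
Title: Pulsatile Hemodynamics of Idealized Type B Aortic Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics of uncomplicated type B
    aortic dissection. Generates idealized two-dimensional true/false-lumen
    geometries parameterized by re-entry (fenestration) tear location,
    solves the unsteady incompressible Navier-Stokes equations on a masked
    staggered grid with PISO-style pressure-velocity coupling and pulsatile
    physiological boundary conditions, and post-processes regional pressure,
    wall shear stress, tear fluxes and false-lumen recirculation across an
    eleven-case re-entry-location sweep, with mesh-sensitivity and analytic
    channel-flow validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
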