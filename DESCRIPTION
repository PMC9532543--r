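Package: cellhammer
Title: Dynamic Compression-Shear Stress Loading on Cultured Cells via
    Projectile-Driven Water Hammer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models a projectile-impact loading rig for cell mechanobiology:
    a projectile strikes the liquid column of a rectangular culture
    microchannel and launches a weak compression front that applies
    MPa-scale compressive stress and synchronous kPa-scale viscous wall
    shear on the cultured cells. Provides Tait equation-of-state
    thermodynamics, weak-shock Rankine-Hugoniot jump relations, an
    impedance-matched exponential impact source pulse, conduit acoustics
    with fluid-structure and continuum design criteria, a
    method-of-characteristics 1D transient water-hammer solver with laminar
    friction, and an impulsively-started boundary-layer wall shear
    estimate, together with YAML configuration, packaged case presets and
    JSON design reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
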