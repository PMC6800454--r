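Package: mtflim
Title: Molecular Tension FLIM and Force Microscopy Analysis for Fluid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for molecular tension probes on
    supported lipid bilayers imaged by fluorescence lifetime (TCSPC fast-FLIM),
    excitation-resolved polarization (molecular force microscopy), and
    photobleaching recovery (FRAP). Converts photon-count image cubes into
    per-pixel maps of barycenter lifetime, percent-open tension probes and
    relative probe density; detects and tracks podosomes, quantifies core
    depletion and ring tension statistics; recovers probe tilt and azimuth from
    polarization sweeps; estimates lateral diffusion coefficients; and evaluates
    a geometric ring model of net podosome tensile force. Includes a seeded
    photon-realistic scene simulator so every analysis stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
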