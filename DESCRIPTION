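Package: protonflux
Title: Proton Translocation Analysis for Second-Harmonic Membrane Imaging and Bilayer Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies proton translocation across free-standing lipid bilayer
    membranes from second-harmonic (SH) microscopy stacks and current-voltage
    recordings. Implements the Goldman reversal-potential inversion for ion
    permeability ratios, Goldman-Hodgkin-Katz (GHK) flux-equation permeabilities,
    a Gouy-Chapman-Stern surface-potential solver, SH-intensity to transmembrane
    potential conversion with parallel-plate capacitor charge accounting, domain
    segmentation with occurrence histograms, per-ROI exponential decay-constant
    and flux mapping, Boltzmann-weighted pore-permeability profiles along the
    chain coordinate, and an analytic water-needle stabilization-energy model.
    Seeded synthetic-data generators emulate the microscope and patch amplifier
    so every pipeline stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
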