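Package: txac
Title: Transmission-Based Hardware Attenuation Correction for PET/MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates 511 keV linear attenuation coefficient (mu) maps of
    MR-invisible hardware (patient table, RF arrays, phantoms) from a blank
    scan and a transmission scan acquired with a static Ge-68 line source on
    a cylindrical PET scanner. Provides a scanner and acquisition simulator
    (line-of-response enumeration, Siddon ray tracing, Beer-Lambert forward
    model with optional Poisson noise), the Beer-Lambert inversion that
    estimates a homogeneous hardware LAC and assembles the per-voxel mu-map,
    theoretical compound LAC computation from embedded elemental
    mass-attenuation tables, the bilinear CT Hounsfield-unit-to-LAC
    comparator, and comparison metrics (voxel-wise relative percentage
    difference, count histograms, AHA 17-segment polar maps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    RNifti
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
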