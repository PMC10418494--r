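Package: abaffinity
Title: Antibody-Antigen Binding Affinity from Structures and Solution Equilibria
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two complementary routes to the binding free energy of
    antibody-antigen complexes. A structure-based route evaluates a
    contact-based QSAR model on atomic coordinates: interfacial
    residue-residue contacts classified by physicochemical character,
    non-interacting surface composition from Shrake-Rupley solvent-accessible
    surface areas, and buried surface area. A solution-phase route converts
    species concentrations measured by multi-detector size-exclusion
    chromatography into the Goldberg bivalent-antibody association constant
    and its free energy, including single-standard detector calibration,
    chromatogram peak deconvolution, absolute molar mass from light
    scattering, and forward equilibrium simulation for parameter recovery.
    Rigid-body superposition, antigen grafting and steric-clash reporting
    support stoichiometry analysis of 2:1 antigen-antibody complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
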