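Package: eacfield
Title: Electric-Field-Based Equivalent Atomic Charges for QM/MM Interaction Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how QM/MM electrostatic interaction energies between a
    diatomic CO probe and its protein surroundings relate to the electric field
    along the probe bond. Computes point-charge electrostatic potentials and the
    mean field along the bond, decomposes supplied total and gas-phase energies
    into interaction energies, fits sign-segmented linear models of energy
    against field, derives electric-field-based equivalent atomic charges (EAC)
    under a constant-moment dipole model, corrects low-level interaction
    energies toward a high-level target, and classifies ligand orientational
    states (B1/B2) from Fe...C=O angles. A synthetic-data module generates
    trajectories with the statistical structure of QM/MM molecular dynamics so
    the whole pipeline is testable without a quantum-chemistry engine.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
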