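Package: blocklen
Title: Side-Chain Distal-Block Length and Torsion Profiling for Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical characterization of protein side-chain conformations
    using four internal-coordinate features: the backbone torsion angles phi
    and psi, the first side-chain torsion chi1, and the distal-block length
    (the distance from the alpha carbon to the mass center of the side
    chain's terminal rigid group). Reads PDB coordinate files with
    configurable chain and alternate-location selection policies, bins
    features into peak-normalized probability-density profiles and 2D
    histograms, detects peaks and compares two structure sets (for example
    crystallographic versus cryo-EM models). Includes an internal-coordinate
    conformer generator that builds single side chains and short peptides at
    exact user-specified torsions from standard covalent geometry, producing
    valid PDB files with ground-truth feature tables for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ggplot2,
    lattice,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
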