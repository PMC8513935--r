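Package: ssipsolv
Title: Surface Site Interaction Point Model for Solvation and Partition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based assignment of discrete hydrogen-bond donor (alpha) and
    acceptor (beta) surface site interaction points (SSIPs) to organic
    molecules from SMILES, and the empirical free-energy machinery built on
    them: per-site solvation free energies in simple and two-domain (polar)
    solvents, whole-molecule solvation and solvent-to-solvent transfer free
    energies, partition coefficients, 1:1 hydrogen-bond complexation free
    energies, and rmsd-minimisation calibration of solute and solvent
    descriptors against experimental partition data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
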