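Package: vwfshield
Title: Steric-Shielding and Mechano-Presentation Analysis for Force-Unfolded
    Protein Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trajectory analysis of mechanosensitive protein modules such as
    the von Willebrand factor (VWF) D'D3-A1-A2-A3 mechanomodule. Quantifies
    epitope accessibility as steric clashes between a superposed static
    receptor reference (GPIb-alpha) and dynamic autoinhibitory regions and
    glycans; detects hydrogen bonds and salt bridges with geometric criteria
    and builds across-replicate contact-frequency maps with a persistence
    filter; computes structural descriptors (RMSD, RMSF, radius of gyration,
    Shrake-Rupley SASA); analyses steered-pull force-extension profiles and
    rupture forces; and maps simulated pull rates onto physiological shear
    stress via the Newtonian relation. Includes a seeded coarse-grained
    bead-model simulator of force-induced uncoiling with a complete per-frame
    ground-truth log, so every analysis stage is testable against a planted
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
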