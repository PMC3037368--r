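Package: alacoil
Title: Alanine-Zipper Coiled-Coil Detection, Model Building and Interface Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sequence and structure analysis of Alanine-zipper (Alacoil)
    coiled-coil dimerization domains of the kind found in plant group II
    BBR/BPC GAGA-binding transcription factors. Detects heptad registers,
    Ala-core zipper motifs with flanking charge complementarity and basic
    nuclear localization signal motifs in protein sequences; builds
    reduced-atom parametric alpha-helix and coiled-coil dimer models at
    native or shifted registers with core-swap mutants; inventories
    intermolecular salt bridges and hydrogen bonds; and scores dimers with
    an MM-PBSA-style binding free-energy decomposition using a
    generalized-Born polar term and a surface-area nonpolar term. A seeded
    synthetic-data generator emulates group II BPC-like proteins and dimer
    fixtures so the full pipeline runs and is testable without external
    structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
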