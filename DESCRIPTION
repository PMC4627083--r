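Package: zfmode
Title: Binding-Mode-Aware DNA Specificity Analysis for C2H2 Zinc Fingers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how neighbouring C2H2 zinc-finger domains
    modulate DNA binding specificity. Detects zinc fingers and their
    inter-finger boundary residues (+9 of the preceding finger, -2 of the
    subject finger) in protein sequence, extracts adjacent two-finger
    arrays from protein-DNA complex structures, clusters their Calpha
    geometries into discrete binding modes, builds mode-resolved
    residue-to-base preference profiles from gold-standard motif data, and
    predicts binding motifs (position weight matrices) with a random
    forest whose covariates optionally include the boundary-pair residues.
    Includes motif I/O (MEME minimal, JASPAR), occupancy-based affinity
    scoring and motif similarity, Affinity Propagation redundancy
    clustering, and a planted-truth simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
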