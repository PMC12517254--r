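Package: dynatile
Title: Discovery of Embedded Ferredoxin-Like Domains by Comparative Protein Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects small iron-sulfur binding domains (bacterial
    ferredoxin-like folds) embedded inside large multidomain
    oxidoreductases by comparing residue-level dynamics. Coarse-grained
    normal modes are computed from an anisotropic elastic network built
    on alpha-carbon coordinates, converted to residue cross-correlation
    matrices, and compared between a small query protein and a large
    target over all contiguous sequence tiles. Dynamical (cosine),
    structural (Frobenius/Gower) and sequence (Smith-Waterman)
    similarities are combined with weights chosen by Gaussian-process
    Bayesian optimization, candidate regions are filtered by
    cysteine-iron coordination geometry, segmented into islands, and
    traversed with a dynamic-programming optimal-path algorithm to map
    matched tiles back onto the target structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
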