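Package: gpcrprofile
Title: Binding-Site Profiling and Profile Alignment for GPCR Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes ligand-bound G protein-coupled receptor (GPCR) binding
    interactions as one-dimensional per-helix integer profiles using reduced
    physico-chemical residue alphabets (the 8- and 10-digit profiling schemes),
    aligns profiles between receptor pairs with Smith-Waterman local dynamic
    programming under group-reduced substitution matrices (BLOSUM62-derived,
    residue-matrix-derived, identity or custom), and computes normalized
    alignment scores N = T/R that rank drug-repurposing candidates. Includes
    binding-site detection by distance cutoff from structure files, dihedral
    based transmembrane-helix assignment, an all-vs-all screening driver with
    threshold filtering, and a synthetic seven-helix-bundle fixture generator
    with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
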