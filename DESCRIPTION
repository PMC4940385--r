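Package: phonogeom
Title: Geometry of Phonological Segment Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the geometric structure of phonological
    segment inventories encoded in a binary distinctive-feature system.
    Computes economy (Econ), local symmetry (Loc, a rank-normalized count
    of minimal pairs) and global symmetry (Glob, a rank-normalized feature
    imbalance) for inventories viewed as occupied vertex sets of a feature
    hypercube; searches for irreducible contrastive feature subsets;
    enumerates or samples geometrically distinct configurations to build
    the attainable-value tables used for rank normalization; generates
    four families of size-matched random control inventories; compares
    score distributions with ROC/AUC and bootstrap intervals; and ships a
    synthetic multi-language database generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
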