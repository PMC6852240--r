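Package: surfpatch
Title: Decrypting Protein Surfaces: Interface Patch Prediction and
    Interacting Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interacting patches on protein
    surfaces by combining evolutionary conservation (tree-trace levels
    averaged over sampled distance trees), physicochemical interface
    propensities, local geometry (circular variance) and statistics
    derived from cross-docking pose ensembles (normalized interface
    propensities).  Patches are grown from high-scoring seeds through
    extension and outer layers under four scoring strategies, with an
    iterative consensus.  Experimentally-derived interacting sites are
    extracted from complex structures, mapped across homologs by global
    sequence alignment, and merged into interacting regions; predictions
    are evaluated against them with precision/recall/F1, surface
    coverage and backbone-RMSD conformational variability.  A synthetic
    fixture generator (helical complexes, homolog pools, docking pose
    sets with planted signal) makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    bio3d,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
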