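Package: smialign
Title: Charge-Based Global Alignment of Small Molecules from SMILES
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global alignment of small organic molecules encoded as SMILES
    strings. Atoms are aligned by their Gasteiger partial charges with an
    affine-gap Needleman-Wunsch dynamic program, scored by empirical
    log2-survival matrices built from the charge differences observed in a
    molecule corpus, either pooled over all atoms or per element pair.
    Includes canonicalization-stability diagnostics, alignment validation
    metrics (Levenshtein, exact and Tanimoto similarity), an exhaustive
    gap-penalty parameter sweep, and per-distance alignment-score profiles
    for cyclic and linear metabolic pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
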