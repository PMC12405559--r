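Package: protdesign
Title: Hallucination-Based Protein Design with Pluggable Structure-Prediction Oracles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for hallucination-based protein design.
    Structure-prediction confidence measures (pLDDT, pAE, pTM) are composed
    into modular fitness functions for de novo monomer/oligomer, binder and
    conformational-change design; sequences are optimised with an elitist
    evolutionary algorithm against a pluggable structure-predictor oracle,
    then redesigned by masked autoregressive sampling from a
    structure-conditioned sequence model. Includes self-consistency
    validation (scRMSD, scTM) with success classification and filtering,
    codon optimisation under GC/repeat/hairpin constraints, and the
    statistics for toxin-inhibition colony screens together with a plate
    simulator. A deterministic synthetic folding oracle ships with the
    package so every stage runs without a neural network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
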