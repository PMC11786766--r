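Package: netDTI
Title: Interactome-Constrained Neural Models for Drug-Target and Off-Target
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains ensembles of recurrent neural models constrained by a signed
    prior-knowledge signaling network that map drug doses to transcription-factor
    activities through a chemical-similarity drug layer, then interrogates the
    trained ensemble to infer drug-target interactions by masking-based
    attribution (integrated gradients with an exact linear-algebra oracle),
    estimate off-target effects on transcription factors, and extract consensus
    mechanism-of-action subnetworks. Includes transcription-factor activity
    scoring from regulons, replicate-correlation filtering against a null,
    ECFP4/Tanimoto chemical similarity, network curation and trimming, and a
    synthetic ground-truth generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
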