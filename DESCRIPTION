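Package: immunopep
Title: Peptide Immunogenicity Prediction from Physicochemical Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An HLA-agnostic random-forest classifier of MHC class I peptide
    immunogenicity. Peptides of 9-11 residues are encoded as ordered
    118-dimensional physicochemical feature vectors (per-residue AAindex
    principal components plus eight global descriptors), training sets are
    assembled by non-self filtering against a reference proteome with
    length-stratified subsampling, and downstream analyses cover dataset
    composition diagnostics, benchmark metrics, a tumor max-mean
    immunogenicity biomarker, vaccine epitope prioritization, and survival
    stratification. Seeded synthetic-data generators emulate every input so
    the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    survival,
    Biostrings,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    seqinr,
    withr
Config/testthat/edition: 3
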