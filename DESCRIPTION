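Package: cisplatinsig
Title: Conserved Cisplatin-Associated Gene Sets and TNBC Resistance Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative gene-set analysis for chemotherapy response in
    triple-negative breast cancer (TNBC) subtypes. Projects chemical-associated
    gene sets from mouse and rat into the human identifier namespace, derives
    an evolutionarily conserved cisplatin-associated core by set intersection
    (with a hierarchical-similarity intersection lattice and Jaccard /
    hypergeometric overlap statistics), builds a gene-by-subtype regulation
    matrix from up/down differential-expression sets, extracts the signature of
    genes regulated differently in cisplatin-resistant (LAR, M) versus
    sensitive (BL1, BL2) subtypes, and characterises gene sets by
    ontology-aware term enrichment with true-path annotation propagation.
    Ships transcribed regulation fixtures and a planted-truth synthetic data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
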