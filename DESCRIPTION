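Package: markermine
Title: Terminology-Driven Retrieval and Ranking of Biomarker Literature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for literature-based biomarker candidate discovery.
    Loads hierarchical biomarker terminologies (entity classes with
    synonyms), annotates abstract corpora by deterministic dictionary
    matching, builds an inverted document-frequency index, evaluates
    Boolean class-combination queries, and ranks the genes and proteins
    of a retrieved corpus by document frequency or by their
    Kullback-Leibler (relative entropy) contribution against a reference
    corpus. Includes the accompanying evaluation battery (Cohen's kappa,
    gene-set enrichment curves against a gold standard,
    precision/recall/F-score at recall thresholds) and a seeded synthetic
    corpus generator with planted marker genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stringi,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
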