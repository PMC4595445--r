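Package: pbcouple
Title: Passage-Based Bibliographic Coupling for Inter-Article Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates similarity between full-text scientific articles by
    integrating bibliographic coupling with the context passages that authors
    write around important out-link citations (the PBC measure), together with
    link-based and BM25-based baseline measures and a ranked-retrieval
    evaluation harness (average precision, mean average precision,
    precision-at-k, paired significance tests). Reads PMC JATS/NXML full text
    and a documented JSON corpus dialect, and ships a synthetic citation-corpus
    generator with planted related-article structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
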