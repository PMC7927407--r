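Package: cobm25
Title: Co-Word Augmented BM25 Retrieval of Biomedical Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieval of biomedical abstracts for precision-medicine style
    queries (disease, gene variant, patient demographics). Implements a
    composite ranking function that extends Okapi BM25 with a separately
    normalised score over a document "word list" (chemical substances, MeSH
    headings and author keywords) and a disease-gene co-word score, plus
    query expansion from a static MeSH-style lexicon and demographic age
    mapping. The five free parameters of the ranking function are tuned by
    Cuckoo Search with Levy flights against an average P@10 plus average
    nDCG objective. Includes MEDLINE-dialect XML parsing, TREC-style topic,
    qrels and run file input/output, ranking metrics, and a synthetic
    collection generator with planted co-word driven relevance for hermetic
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
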