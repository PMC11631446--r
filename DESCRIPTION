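Package: conntext
Title: Mining Brain-Region Connectivity Relations from Neuroscience Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts brain-region mentions and directed connectivity relations
    from neuroscience text and assembles them into a literature-backed
    connectivity knowledge graph. Named-entity recognition couples BIO token
    labels with auxiliary start/end position pointers trained under a joint
    cross-entropy loss; relation classification wraps the two candidate
    regions in boundary marker tokens and classifies the pooled marker
    vectors into unconnected, undirected, output and input relations.
    Includes exact and lenient span-matching evaluation with k-fold
    cross-validation, neuroanatomical ontology merging with staged fuzzy
    entity linking, a gazetteer trie used for annotation denoising, and a
    synthetic-corpus generator with known ground truth so the whole pipeline
    is trainable and testable offline with a small deterministic encoder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
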