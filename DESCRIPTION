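Package: veriset
Title: Self-Verifying Functional Annotation of Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage pipeline that names the prominent biological process
    of a gene set with a pluggable text-generation backend, extracts the
    affirmative claims the output makes, verifies each claim against
    expert-curated knowledge sources (enrichment and gene-centric), and
    revises the output accordingly. All external dependencies (language
    model, text encoder, live databases) are contracts with deterministic
    offline substitutes, so the whole system runs and is testable with no
    network access. Ships the full evaluation suite: ROUGE-1/2/L against
    ground-truth names, embedding cosine similarity, background-percentile
    ranking, hop-bounded ontology-ancestor comparison over an OBO graph,
    exact-match enrichment-term testing, Wilson score intervals, and
    batch-sampled aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
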