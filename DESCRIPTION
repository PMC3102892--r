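Package: hypeval
Title: Rule-Based Evaluation of Biological Event Hypotheses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents biological hypotheses as logical compositions (AND, OR,
    XOR) of typed molecular events, retrieves candidate supporting facts from an
    event knowledge base with ontology subsumption reasoning, scores each event
    with configurable per-event-type rule sets normalized as a fraction of the
    maximum attainable points, propagates undecidability through the logical
    operators, and emits linked evaluation reports (JSON and N-Triples)
    connecting scores to the supporting data. Ships a worked knowledge base for
    the yeast galactose (GAL) regulatory network together with generators of
    random knowledge bases for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
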