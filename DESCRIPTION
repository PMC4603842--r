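Package: nanopubr
Title: Nanopublications for Gene-Disease and Genomic-Overlap Assertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts differential-expression and gene-promoter-region overlap
    result tables into nanopublications: RDF named-graph documents pairing a
    minimal scientific assertion with workflow provenance (PROV-O, linked to a
    Research Object) and publication metadata. Ships a small Sequence Ontology
    extension for chromatin states, a quad store with gene/region/GO-closure
    queries and a five-source drug-target integration query with a polar
    surface area prioritization filter, and a seeded synthetic-fixture
    generator (including the packaged drug-target worked example) for
    end-to-end testing. Reads and writes TriG, N-Quads and a Turtle subset
    without blank nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
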