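Package: regkb
Title: Protein-Centric Gene-Expression Knowledge Graphs with Rule-Based Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds protein-centric knowledge graphs for gene-expression
    regulation from ontologies (OBO 1.2), annotation (GAF 2.x), molecular
    interaction (PSI-MI TAB 2.5), pathway, orthology and transcription-factor
    target-gene tables; computes a forward-chaining inference closure driven
    by five relation attributes (reflexivity, transitivity, superrelations,
    compositions, priority over subsumption); evaluates boolean query
    templates for candidate regulators with asserted/inferred provenance
    partitioning; and prioritizes candidates and shared target genes against
    expression evidence. Includes a seeded synthetic knowledge-base generator
    with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, utils, stats, igraph, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
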