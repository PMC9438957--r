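Package: gfabubbles
Title: Bubbles, Superbubbles and Bubble Chains in Bidirected Genome Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects superbubbles, simple bubbles, insertion bubbles and runs of
    linearly connected bubbles ("bubble chains") in bidirected sequence graphs
    such as de Bruijn or pangenome graphs read from GFA1 files. Bubbles arise at
    polymorphic loci (for example heterozygous variants in an assembly graph) and
    enumerate the variation structure of the graph. The package also provides the
    standard utility operations for working with such graphs: compaction of
    linear node stretches into unitigs, extraction of the biggest connected
    component, and extraction of a fixed-size neighborhood around a node. A
    planted-variant diploid de Bruijn fixture generator and an exhaustive
    definitional superbubble oracle support property-based verification, and a
    command-line interface exposes the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
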