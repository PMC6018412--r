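Package: mvlogic
Title: Multi-Valued Logical Modeling of Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Definition, simulation and analysis of multi-valued logical
    models of cellular regulatory networks in the Thomas formalism.
    Models couple discrete components with signed, threshold-indexed
    interactions and logical rules; the package builds state transition
    graphs under asynchronous, synchronous, complete, sequential and
    priority-class updating schemes, computes stable states directly by
    constraint propagation, identifies attractors as terminal strongly
    connected components, compresses dynamics into SCC and hierarchical
    transition graphs, analyses the sign and functionality context of
    regulatory circuits, applies knock-down and ectopic perturbations, and
    reduces models by node elimination while preserving stable states.
    Models are read and written in a plain-text format and graphs can be
    exported as Graphviz DOT or TSV edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
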