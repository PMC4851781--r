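Package: anonlattice
Title: Scalable De-Identification of Tabular Health Data with
    Full-Domain Generalization and Record Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: De-identifies tabular datasets of categorical
    quasi-identifiers using full-domain generalization followed by
    record suppression under the k-anonymity privacy model. Data
    quality is measured with the Iyengar loss model together with a
    monotone generalization-only upper bound. The search over the
    generalization lattice is driven by predictive properties
    (insufficient protection, insufficient quality) maintained
    implicitly as antichains in a rank-annotated prefix tree, and three
    search strategies are provided: an exhaustive oracle, a
    globally-optimal rank-order search with predictive pruning, and a
    best-first branch-and-bound search usable as an optimal or anytime
    heuristic algorithm. Includes synthetic data and hierarchy
    generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
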