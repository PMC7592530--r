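Package: pathtopo
Title: Topology-Aware Upstream/Downstream Analysis of Gene-Set Pairs on a
    Global Interaction Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the upstream/downstream relationship between two gene
    sets (pathways or user-defined functional modules) on a global directed
    gene-gene interaction network. Each gene is weighted by its relative
    position inside its own pathway (the fraction of fellow pathway members
    reachable downstream of it), and a pair of gene sets is scored by the
    weighted tail-to-head cross edges running from one set into the other,
    in both directions. The difference of the two directional influence
    scores is calibrated against an empirical null obtained by permuting
    cross-edge endpoints while preserving each pathway's internal topology
    (shared genes are split into side-specific pseudo-vertices first),
    yielding a normalized score and a permutation p-value. Utilities build
    the global network from edge lists or KGML pathway files, read GMT gene
    sets, compute all-pairs score and Jaccard matrices, and assemble
    significant positive scores into directed weighted "super-module"
    graphs. Includes a synthetic fixture generator for chains, fans, cycles,
    mirrored pathways and planted cascades, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
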