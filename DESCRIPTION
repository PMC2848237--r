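Package: enfrn
Title: Gene Regulatory Network Inference with an Evolutionary Recurrent
    Neuro-Fuzzy Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers signed, scored regulatory interactions between genes
    from short time-course expression data using a five-layer recurrent
    neuro-fuzzy network (ENFRN).  The network structure is grown online by
    a self-organizing clustering of the input and output spaces, pruned by
    binary particle swarm optimization, and fine-tuned by continuous
    particle swarm optimization.  Trained networks are translated into a
    regulation type (activation, repression or none) and a composite
    confidence score via a lag-1 analysis of linguistic-label changes, and
    a three-stage regulator-selection procedure assembles whole networks.
    Includes a generator of synthetic cell-cycle-like expression data with
    known ground-truth edges for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
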