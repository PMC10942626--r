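Package: taskspace
Title: Task-Space Dissection of Muscle Couplings with Information-Theoretic
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pairwise muscle couplings in the task space from
    trial-structured electromyographic (EMG) envelopes. Couplings between
    muscle-timepoint activity vectors and task variables are estimated with
    Gaussian-copula mutual information and classified by co-information into
    task-redundant, task-synergistic and task-irrelevant interactions. The
    resulting multiplex coupling tensors are sparsified at their percolation
    threshold against weight-shuffled null networks, model ranks are selected
    by consensus multilayer community detection, and low-dimensional
    space-time muscle networks are extracted by sample-based non-negative
    matrix tri-factorisation. Includes EMG envelope preprocessing, network
    communicability analysis of the extracted factors, generalisability
    (leave-one-out and random-ablation) protocols, and a synthetic-data
    generator with planted interaction structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    Matrix,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
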