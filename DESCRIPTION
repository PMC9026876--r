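Package: motiveRank
Title: Network-Proximity Prioritization of Candidate Disease Biomarkers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate biomarker proteins against the molecular
    characterization of a disease, modeled as pathophysiological processes
    ("motives") with curated effector protein sets embedded in a multi-layer
    protein interaction network.  Candidate-to-motive relationships are scored
    by graph-proximity features (shortest paths, random walk with restart,
    neighborhood overlap) fed to a small feed-forward neural network trained
    on effector/non-effector truth tables, calibrated to a 0-100 score scale
    via degree-matched permutation nulls and empirical p-values, and banded
    into relationship categories.  Includes selection rules for multi-process
    candidates, a synthetic study generator with planted modules for
    validation, and a reproducible pipeline with TSV/JSON reporting.  Ships
    fixtures transcribed from a published degenerative aortic stenosis
    characterization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    igraph,
    Matrix,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
biocViews: Network, GraphAndNetwork, Classification, SystemsBiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
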