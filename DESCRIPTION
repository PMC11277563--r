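Package: stagemiR
Title: Stage-Specific miRNA Prioritization for Early Oral Oncogenesis
Version: 0.1.0
Authors@R:
    person("stagemiR", "Developers", email = "stagemir@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate microRNAs for the consecutive early
    histological stages of oral squamous cell carcinoma (hyperplasia,
    dysplasia, early invasion). Candidates are scored by simultaneous
    coverage of stage-specific directional gene panels derived from a
    hamster model of sequential oral oncogenesis, filtered by a strict
    greater-than-75-percent target-score threshold, and required to show
    the reverse expressional dysregulation in tissue or saliva evidence.
    Includes curation of dysregulation evidence, bipartite miRNA-gene
    network handling with GraphML/JSON export, cross-stage set algebra,
    a seed-site scanner for 3'UTR sequences, and a synthetic-data
    generator with planted candidates and decoys for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
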