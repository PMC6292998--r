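Package: connectomekb
Title: Semantic Knowledge Base for Multimodal Connectome and Transcriptome Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents macroscale brain connectivity as a semantic network: brain
    coordinates, atlas entries, ontology terms and brain structures are typed
    semantic objects, and structural or functional connections are typed, directed
    relations between them. Experiments store subject-indexed measurements where
    the subject may itself be a relation (a connection), so connectivity matrices
    from DTI and resting-state fMRI become queryable data. An existential
    path-query engine with ontology is-a expansion extracts functional brain
    network templates, filters localized gene expression (Allen Human Brain Atlas
    microarray style), and joins connectivity with differential gene-expression
    counts between brain structures. Includes download-free synthetic generators
    with planted statistical structure and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
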