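Package: avwm
Title: Large-Scale Neural Network Simulation of Auditory-Visual Working
    Memory and Intersensory Attention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a large-scale cortical network model of auditory and
    visual object working memory built from Wilson-Cowan excitatory/inhibitory
    microcircuits. The auditory stream (A1, A2, ST, MTL, prefrontal FS/D1/D2/R)
    and a symmetric visual stream (V1/V2, V4, IT, EC, prefrontal units) are
    coupled through a mutually inhibitory anterior-insula pair that computes
    salience-driven exogenous attention; endogenous attention is a task-set
    bias on prefrontal delay units. The package runs delayed match-to-sample,
    distractor, Sternberg list-memory, bimodal-competition and memory-load
    tasks; scores behavioral accuracy; and converts integrated synaptic
    activity into region-wise BOLD fMRI time series with a balloon
    hemodynamic model for block and event-related designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
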