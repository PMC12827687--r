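Package: remapnet
Title: Energy-Efficient Recurrent Networks of Active Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how predictive
    remapping across saccades and allocentric fixation coding emerge in
    recurrent neural networks trained only to minimize metabolic energy
    consumption, proxied by mean absolute unit preactivation. Provides a
    synthetic active-vision world (1/f-filtered gray-scale scenes, scanpaths,
    fixation crops, saccadic efference copies), a fully connected recurrent
    network with fixed excitatory input drive and bottom-up, lateral, and
    top-down connections, hand-derived backpropagation-through-time training
    under energy, categorization, and temporal-contrastive objectives, a
    battery of static and dynamic control predictors, linear decoding of
    allocentric fixation coordinates, targeted in-silico lesioning, feedback
    similarity analyses against ideal inhibition, spatial-memory analyses,
    and clustering of allocentric-coding units.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
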