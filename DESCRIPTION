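Package: SynConnect
Title: Synaptic Site Segmentation and Neuron Connectivity from Expansion
    Light Sheet Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies synaptic connectivity between fluorescently labeled
    neurons in expanded-tissue light sheet microscopy (ExLLSM) volumes.
    Provides 3D volume I/O (TIFF series and a chunked N5-like store),
    neuron-mask post-processing (thresholding, iterative gap bridging,
    morphological closing, component size filtering), punctate synaptic-site
    instance segmentation (probability map, distance-transform watershed,
    size gates), voxel-colocalization assignment of sites to neuron masks
    and neuron-to-neuron connection counting, blockwise processing of large
    volumes with cross-block label merging, instance-level detection
    evaluation (precision/recall), and a synthetic phantom generator with
    full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
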