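Package: synapseCensus
Title: Synapse Quantification in Volume Electron Microscopy Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying chemical synapses in focused ion beam /
    scanning electron microscopy (FIB/SEM) image stacks of cortical neuropil.
    Provides a seeded synthetic-neuropil generator with exhaustive ground
    truth, 3D synaptic-junction segmentation by Gaussian smoothing,
    gray-level thresholding and connected-component extraction, classification
    of junctions as asymmetric or symmetric from postsynaptic-density
    thickness, unbiased counting-frame (brick) stereology with tissue
    shrinkage correction, postsynaptic-target annotation (spine head, spine
    neck, dendritic shaft, truncated; spiny versus not-determined dendrites;
    multi-synapse spines), and the accompanying statistical analysis
    (per-layer percentage and density tables, contingency-table expected
    counts and enrichment ratios, chi-squared, Kruskal-Wallis and
    Mann-Whitney tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
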