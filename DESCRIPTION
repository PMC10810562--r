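Package: nicheQuant
Title: Quantitative Imaging of Stem-Cell Niche Aging in the C. elegans Gonad
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify aging of the distal tip cell (DTC) niche and
    the germline stem cell (GSC) pool of the Caenorhabditis elegans gonad
    from multi-channel 3D widefield stacks. The package reconstructs
    spherical germ-cell nuclei from the DAPI channel by per-plane circular
    Hough detection and cross-plane sphere assembly, calls active
    transcription sites (ATS) and single mRNAs from intron/exon smFISH
    channels with intron-exon colocalization and single-mRNA intensity
    normalization, assigns spots to cells by a radius-capped Voronoi rule,
    and computes the spatial statistics of Notch activation: percent-positive
    gradients with pool boundaries and peaks, DTC nuclear drift, distances of
    activated cells to the niche nucleus, nearest-neighbour distances,
    progenitor-zone extent, and membrane morphology of the DTC cap,
    processes, gaps and fragments. A seeded generative model of an aging
    distal gonad renders realistic synthetic stacks with ground truth, so
    every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
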