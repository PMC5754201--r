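Package: nichechart
Title: Depth-Profile Quantification of Glial Niche Architecture in Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the architecture of the neural-stem-cell (NSC) niche
    from multi-channel confocal Z-stacks. Builds chamber organisation charts
    (per-channel mean intensity versus imaging depth with three-point
    parabolic sub-slice peak refinement), computes peak depth offsets of NSC
    and neuron channels relative to the cortex-glial top layer, measures the
    membrane-to-NSC ratio, thresholded neuronal volumes and marker-positive
    nuclei counts, and reports group comparisons with unpaired Student's
    t-tests, mean plus or minus SEM summaries and five-number whisker
    summaries. Includes a seeded synthetic 3D scene generator with ground
    truth (ordered fed-type and collapsed starved-type niche geometries) so
    that every pipeline stage is verifiable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
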