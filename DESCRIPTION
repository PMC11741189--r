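Package: adipoquant
Title: Quantification of Adipocyte Differentiation from Two-Channel Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipelines for iPSC-derived adipocyte cultures stained
    with DAPI (nuclei) and BODIPY (neutral-lipid droplets). Implements nuclei
    counting from the DAPI channel (constant background subtraction, Gaussian
    low-pass filtering, Laplacian-of-Gaussian blob detection), lipid-droplet
    segmentation from the BODIPY channel (rolling-ball background correction,
    difference-of-Gaussian enhancement, fixed manual threshold, particle
    analysis), and the derived per-field metrics: differentiation efficiency,
    mean droplet size, and per-cell lipid content with five-region random cell
    sampling. Includes a synthetic two-channel confocal field generator with
    complete ground truth for end-to-end validation, and relative
    gene-expression fold changes by the 2^-ddCt method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
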