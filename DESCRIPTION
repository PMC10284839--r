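Package: imcTopo
Title: Tissue Topology Analysis for Imaging Mass Cytometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for spatial single-cell analysis of
    multiplexed imaging (imaging mass cytometry) data: spillover
    compensation, median denoising and contrast enhancement of channel
    stacks; connected-component nuclei segmentation with
    nuclei-distance artifact filtering and per-cell marker
    quantification; graph-based phenotype clustering of the cell by
    marker matrix; cellular-neighborhood (CN) detection from
    k-nearest-neighbor composition windows with K-means; permutation
    tests for pairwise cell-type interaction and avoidance per region
    of interest; and non-negative Tucker decomposition of the patient
    by CN by cell-type frequency tensor into coupled CN/cell-type
    tissue modules. Includes a ground-truthed synthetic tissue
    generator (clustered point processes with planted niches,
    attraction/avoidance, spillover and patient batch effects) so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    igraph,
    RANN,
    deldir,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    data.table,
    digest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pheatmap,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
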