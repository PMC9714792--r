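Package: vascell
Title: Single-Cell Statistics and Vessel-Image Quantification for Pulmonary Artery Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing pulmonary-artery single-cell RNA-seq data and
    transverse vessel immunofluorescence images. Implements quality-control
    filtering on mitochondrial fraction and detected-gene bounds,
    library-size log-normalization, Wilcoxon rank-sum cluster-marker statistics
    with Bonferroni correction, control-gene-matched signature and cell-cycle
    scoring, arcsine-transformed cell-type proportion tests, Fisher exact
    gene-set enrichment, additive ligand-receptor communication scoring between
    cell populations with a label-permutation null, radial fluorescence
    intensity profiling of vessel walls, Yen-threshold nucleus segmentation
    with medial-layer assignment and marker-positivity quantification, and a
    synthetic-data generator with known ground truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    EBImage,
    tiff,
    jsonlite,
    fgsea,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests: testthat (>= 3.0.0), igraph, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
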