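Package: voxelOmics
Title: Voxelwise Mapping of Brain Coexpression and Comethylation Modules onto MRI Microstructure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An "imaging omics" toolkit for relating brain omics to MRI
    microstructure in subject-matched cohorts. Detects coexpression and
    comethylation modules by consensus clustering of the feature-feature
    Pearson correlation matrix, computes per-subject module average levels,
    removes covariate and neuropathology effects with per-voxel linear models,
    maps module levels onto voxelwise transverse relaxation rate (R2) volumes
    with Benjamini-Hochberg false discovery rate control and cluster-extent
    filtering, scores gray-matter impact of significant white-matter regions
    from streamline-connectivity tables, builds module-trait association
    grids, quantifies incremental variance explained in cognitive decline,
    and annotates modules by hypergeometric gene-set over-representation.
    Includes a synthetic-data generator that plants known module structure,
    voxel couplings, pathology confounding and trait effects so that every
    stage is testable against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    RNifti,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
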