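Package: lesionmap
Title: Voxel-Wise Permutation Mapping and Stereology for Catecholaminergic
    Lesion Volumes
Version: 0.1.0
Authors@R:
    person("lesionmap", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative mapping of tyrosine-hydroxylase-positive (TH+) cell
    and fiber changes in 3D brain volumes after unilateral 6-OHDA lesioning.
    Implements voxel-wise permutation statistics for a 2x2 (side x treatment)
    design, Benjamini-Hochberg false discovery rate correction with
    cluster-size-constrained q selection, 3D cluster labelling and direction
    splitting, cluster-level cell and fiber density validation in tissue
    space, region-wise 3D cell counting against a labelled atlas, and
    optical-fractionator stereology. A synthetic-data module generates toy
    bilateral atlases and lesioned cohorts with known ground truth so the
    whole pipeline is testable without imaging data. Volumes are exchanged as
    uncompressed NIfTI-1 files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
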