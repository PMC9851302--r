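Package: voxmesh
Title: Watertight Surface Remeshing of Meshes, Volumes and Morphology Skeletons
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelization-based remeshing engine for neuroscience geometry. Converts
    non-watertight triangle soups, binary and grayscale volumes, and neuron, astrocyte
    and vasculature morphology skeletons (SWC) into watertight, optimized triangular
    surface meshes and bit-packed voxel volumes. Implements conservative surface
    voxelization, parallel-by-slice and three-way solid voxelization, isosurface
    extraction, cotangent-weighted Laplacian smoothing with inflate damping,
    angle-based adaptive coarsening, an iterative watertightness repair loop, and
    tubular sweep / packing-sphere / soma-deformation proxy geometry synthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
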