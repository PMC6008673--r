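Package: voxelflow
Title: Dataflow-Graph Processing, Filtering and Rendering of Volumetric Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A rapid-prototyping toolkit for multidimensional (1D-3D) image
    data, built around a typed dataflow graph: volumes flow along edges
    between processing nodes, parameter changes propagate dirty flags
    downstream, and execution is topological with per-node timing. Ships a
    node library (separable Euclidean distance transform, 27-voxel median
    filter, min/max/average region filters, separable convolution and
    Gaussian blur, derivative and surface-normal extraction, mean curvature,
    intensity rescaling, thresholding, element-wise arithmetic, slice
    extraction, type conversion), automatic tiled execution with halo
    regions, a multi-mode CPU volume ray-caster with red/cyan anaglyph
    stereo, runtime-compiled per-voxel expression kernels with parameter
    introspection, and a compressed (ZStandard) volume file format with a
    plugin interface for standard image formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    png,
    tiff,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
SystemRequirements: libzstd
Config/testthat/edition: 3
RoxygenNote: 7.3.3
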