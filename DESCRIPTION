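Package: trabecula
Title: Virtual Isolation and Topological Analysis of Cancellous Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes cancellous (trabecular) bone in binary micro-CT
    volumes. Provides a semi-automatic five-step dilation/erosion protocol
    that separates the cancellous compartment from cortical bone and
    marrow voids, a topology-preserving 3D thinning stage that reduces the
    cancellous lattice to a skeleton graph of nodes and branches, and five
    complexity indices computed on that graph: node density (kernel
    density over a regular 3D grid, nodes per cubic centimetre),
    trabecular angle against a homologous reference axis, connectivity
    (mean branches per non-terminal node), tortuosity (arc over chord
    length per branch) and box-counting fractal dimension. Includes
    readers and writers for TIFF stacks, NIfTI-1 volumes and Amira
    LandmarkSet / SpatialGraph ASCII files, and a phantom generator that
    produces shell-plus-lattice test volumes with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    RNifti,
    tiff,
    jsonlite,
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
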