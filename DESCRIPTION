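Package: tetrasim
Title: Spatial Stochastic Reaction-Diffusion Simulation on Tetrahedral Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry preparation, spatial Gillespie simulation, and
    visualization-side computation for voxel-based stochastic
    reaction-diffusion models on tetrahedral meshes. Provides mesh import
    (Abaqus, TetGen, Gmsh), dual source/internal element indexing,
    bounding-object element selection, compartments, patches and named
    region-of-interest datasets with an XML archive format; a synthetic
    geometry generator for boxes, smooth and spiny dendrites and nested
    two-compartment solids; an exact direct-method stochastic simulation
    algorithm extended with inter-tetrahedron diffusion and surface
    reactions on membrane patches; uniform-in-simplex render-point
    generation with density capping; and quantitative spatial and temporal
    outputs (axial distributions, synchronized time series).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    xml2,
    stats,
    utils,
    grDevices,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
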