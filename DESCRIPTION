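Package: TriSynapse
Title: Three-Colour 3D dSTORM Analysis of Tripartite Synapses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for three-colour 3D single-molecule
    localisation microscopy (dSTORM) of tripartite synapses: reading and
    writing localisation tables, a synthetic-data generator emulating
    presynaptic (bassoon) and postsynaptic (Homer1) label discs in
    trans-synaptic apposition with perisynaptic astrocytic GLT-1 clouds, a
    minimal biplane localiser with bead-stack PSF calibration, affine
    channel registration from fiducial beads, DBSCAN clustering of
    localisation point clouds with convex-hull morphometry, synapse
    identification as opposed cluster pairs, perisynaptic nearest-neighbour
    distance statistics, and density-weighted rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, jsonlite, yaml, tiff, png
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SingleCell, Spatial, Clustering, Visualization
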