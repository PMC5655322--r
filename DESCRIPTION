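Package: hornfold
Title: Discrete-Shell Simulation of Epithelial Furrow Unfolding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mesh-based simulation of how folded epithelial sheets unfold
    into three-dimensional shapes, motivated by beetle horn morphogenesis.
    A triangulated sheet carries quadratic elastic energies penalising
    deviations of enclosed volume, facet areas, edge lengths and
    inter-facet (dihedral) angles from a stress-free reference state.
    Unfolding is simulated by steepest-descent relaxation, either by
    inflating a closed surface through a time-dependent rest volume or by
    flattening a local furrow patch whose rest dihedral angles are set to
    pi. Includes a synthetic generator for furrow-pattern height maps and
    virtual primordium meshes, shape metrics (expansion ratios, anisotropy,
    planarity, angle-deficit curvature), and OFF/OBJ/PLY mesh input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
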