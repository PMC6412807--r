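Package: tunneltess
Title: Protein Channel Detection by Tetrahedral Tessellation of Heavy Atoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and quantifies ligand access channels to buried protein
    active sites from crystal structures. Heavy atoms are tessellated into
    Delaunay tetrahedra; every shared triangular face is a "door" scored by
    the diameter of the widest disc that clears the van der Waals spheres of
    its three vertex atoms (CVmax). Thresholding the resulting facial graph
    at a ligand thickness CV yields channels (components linking the protein
    exterior to the active site), the limiting ligand size CVlim (bottleneck
    or widest-path value), minimal cost paths extracted by Dijkstra's
    algorithm with edge cost CV/CVmax, and their clustering into trajectories.
    Channel volumes, boundary surfaces, lining residues, egress secondary
    structures, a cylindrical ligand-thickness model, synthetic shell
    fixtures with analytic ground truth, and two PDB visualization export
    modes are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: python (>= 3.8) with scipy, on the PATH (Delaunay
    tessellation backend via Qhull)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
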