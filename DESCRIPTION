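Package: xbondr
Title: Halogen-Bond Geometry, Occupancy and Active-Site Screening for
    Protein-Ligand Structures and Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric detection of C-X...Y and C-X...pi halogen bonds in
    protein-ligand structures and multi-model PDB trajectories, with
    per-residue interaction occupancy statistics, catalytic key-distance
    tracking (e.g. nitrile carbon to catalytic cysteine SG), a wild-type
    referenced mutant screening rule on key-distance means, sigma-hole
    extra-point placement with charge bookkeeping, and a synthetic
    active-site generator that plants halogen-bond geometries and
    key-distance distributions for fully reproducible testing.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
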