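Package: episurf
Title: Conformational B-Cell Epitope Prediction from Antigen Surface
    Geometry, Contact Energies and Residue-Pair Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts conformational B-cell epitopes on antigen protein
    structures. The antigen is discretized onto a voxel grid and its
    solvent-exposed shell is extracted with 3D mathematical morphology
    (dilation and erosion by digital balls); per-atom and per-residue
    surface rates are computed from the shell. Surface residues are
    ranked by a trainable knowledge-based heavy-atom contact potential,
    high-energy well-exposed residues seed candidate epitope patches,
    and patches are re-scored with a normalized log-odds index of
    geometrically related amino-acid pairs learned from labelled
    epitope/non-epitope surfaces. The package ships a deterministic
    synthetic-antigen generator with planted epitope patches and
    pseudo-antibody complexes, plus a full evaluation harness
    (interface-derived ground truth, confusion metrics, 10-fold
    cross-validation over score-weight grids).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
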