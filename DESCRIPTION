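Package: ccmr
Title: Coiled-Coil Search Models, Restraints and Solution Triage for
    Molecular Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing coiled-coil molecular-replacement search
    models from ab initio decoy sets. Builds ideal alpha-helices from backbone
    dihedrals and Cn-symmetric coiled-coils from the Crick parameterization,
    generates seeded noisy decoy ensembles, clusters and truncates decoys into
    polyalanine search ensembles, emits Rosetta-style flat-harmonic distance
    restraints and Cn symmetry definitions for unbiased oligomeric coiled-coil
    modelling, prepares oligomers for the crystallographic asymmetric unit,
    measures coiled-coil geometry (rise, residues per turn, pitch, crossing
    angle, supercoil handedness) and knobs-into-holes packing, and triages
    candidate crystallographic solutions from multi-metric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
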