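Package: cdr3torso
Title: Knowledge-Based Dihedral Restraints for the Antibody HCDR3 Torso
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives knowledge-based backbone dihedral restraints for the
    torso region of the antibody heavy-chain CDR3 (HCDR3) loop from
    crystallographic backbone structures.  Provides circular statistics
    (circular mean and approximate circular standard deviation) over
    phi/psi dihedral samples, greedy RMSD-threshold clustering to separate
    bulged from non-bulged torso conformations, emission of circular-harmonic
    dihedral restraints in Rosetta constraint-file format, and evaluation of
    loop-model decoy sets with length-normalized RMSD (RMSD16), score-based
    recovery metrics and Calibur-style cluster reports.  A synthetic-fixtures
    module builds backbones from specified phi/psi/omega angles so that every
    analysis can be exercised without downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
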