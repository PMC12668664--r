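Package: epiblock
Title: Antibody Epitope Footprints, Interface Geometry, and Binding
    Kinetics for MHC Class I Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural and biophysical analysis of antibody/MHC class I
    complexes and their competition with natural killer cell receptors.
    Reads PDB and mmCIF coordinates, assigns semantic chain roles (MHC
    heavy chain, beta-2 microglobulin, peptide, antibody heavy/light,
    receptor), and computes heavy-atom interface contacts at a distance
    cutoff, Shrake-Rupley solvent-accessible surface areas and buried
    surface areas, Kabsch rigid-body superpositions, cross-complex
    footprint overlap on a shared ligand, receptor-transplant steric
    clash analysis, and per-position peptide contact profiles.  Also
    simulates and fits single-cycle-kinetics surface plasmon resonance
    sensorgrams under the 1:1 Langmuir model, and computes post-hoc
    molecular dynamics trajectory statistics (aligned backbone RMSD
    series, RMSD probability distributions, per-residue RMSF).
    Seeded synthetic-data generators (ideal helices, toy antibody-antigen
    complexes with designed contact distances, harmonic-jitter
    trajectories, closed-form two-sphere surface areas) provide ground
    truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
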