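---
title: "Dissecting antibody and receptor footprints on MHC class I: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting antibody and receptor footprints on MHC class I: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiblock)
```

## The scientific question

An antibody that binds a conserved surface of MHC class I (HLA-A/-B/-C)
can sterically block the inhibitory killer immunoglobulin-like receptors
(KIR) that read the same surface, releasing natural killer cells from
inhibition.  Establishing that mechanism structurally requires a chain of
quantitative analyses: describing the antibody/HLA interface (which
residues touch, how much surface is buried), comparing the antibody's
footprint with KIR footprints on a shared residue numbering, transplanting
a receptor from its own complex into the antibody complex to test whether
both can bind at once, measuring the binding affinity by surface plasmon
resonance (SPR), and summarizing molecular dynamics (MD) trajectories of
epitope variants.  `epiblock` implements that chain as composable,
seed-reproducible operations, each testable against synthetic inputs with
known ground truth.

## Structure representation and chain roles

Coordinates are held as a flat atom table (one row per atom) wrapped in a
`structure_model`; PDB and mmCIF reading is delegated to `bio3d`.  Author
residue numbering is used everywhere, because HLA epitope residues are
cited in mature-protein numbers (K146, R145, ...) that are shared across
allelomorphs; sequential indices would silently break cross-complex
comparisons.  Three parsing policies are fixed:

* only the first model of a multi-model file is read (deposited
  single-particle and crystal models carry one model; multi-frame files
  are trajectories and go through `read_trajectory()`);
* alternate locations keep the highest-occupancy conformer, ties
  resolving to altloc `A` — the common convention; the deposited models
  this package targets carry few altlocs, so the choice is not
  load-bearing;
* waters are excluded by default and HETATM records carry a flag, so
  glycans and ions never enter protein-residue counts or interface areas
  unless asked for.

Chains get semantic roles (`mhc_heavy`, `beta2m`, `peptide`, `ab_heavy`,
`ab_light`, `receptor`) either from explicit hints or from a length
heuristic (peptide at most 15 residues, beta-2 microglobulin 95-105, the
MHC heavy chain the longest chain whose numbering covers the
alpha1-alpha2 platform).  Any rule matched by two chains is an error that
lists the candidates: guessing between two nine-residue chains would be
worse than failing.  Named segments are registered on the heavy chain.
The literature uses three different spans for the "alpha2-1 helix"
depending on context — Q141-Q155 for the epitope, 131-155 for sequence
alignments, 127-158 for the MD fragment — so all three are stored
(`alpha2_1`, `alpha2_1_ext`, `md_fragment`) and every report records
which one it used rather than guessing a single authoritative range.

## Interface description

**Contacts.**  A contact is a heavy-atom pair from different groups
within 4.0 Å, the flat distance criterion used for published interface
tables of this system.  No angular hydrogen-bond geometry is applied:
the deposited models lack hydrogens, and reproducing a specific
contact-typing program's geometry rules would add dependencies without
changing contact existence.  Classification (hydrogen bond when both
atoms are N/O within 3.5 Å; salt bridge for carboxylate/basic-nitrogen
pairs within 4.0 Å, taking precedence) is advisory metadata.  The
spatial-grid acceleration is required by its tests to agree exactly with
a brute-force all-pairs scan, which stays in the package as
`method = "brute"`.  Published tables show only the closest contact per
residue pair; `reduce_closest()` reproduces that reduction with a
deterministic tie-break on atom names.  One borderline case is worth
knowing about: a light-chain asparagine contacts the peptide's position-8
side chain at 3.6-4.3 Å, straddling the 4.0 Å default — the cutoff is a
parameter everywhere precisely so that 4.5 Å reports can be generated
without changing the default.

**Surface areas.**  Solvent-accessible surface area uses the
Shrake-Rupley construction: a deterministic golden-spiral lattice
(default 960 points) on each atom's probe-expanded sphere
(`r_vdw + 1.4` Å), counting points not buried inside any neighbor.
Radii are Chothia-type values (C 1.70, N 1.55, O 1.52, S 1.80 Å);
unknown elements default to 1.70 Å with a warning, or an error in
strict mode.  The per-atom area is exact for an isolated atom by
construction, and the two-sphere closed form (`two_sphere_sasa()`)
provides an independent oracle: at 960 points the lattice agrees with it
to better than 1%.  Because the lattice is fixed in the laboratory
frame, SASA is rotation invariant only up to that same discretization —
the invariance tests therefore use a ~1% tolerance rather than machine
precision, and doubling the point count is the convergence check.

**Buried surface area.**  `interface_area()` computes SASA three times
(each group alone, then the complex) and always reports both conventions:
`bsa_total` (the summed burial of both sides) and `bsa_half`
(total/2, the per-interface area).  Published BSA figures for
antibody/antigen interfaces in this system (~900 Å² for the Fab, ~750
and ~920 Å² for the two KIR complexes) are typical of the half
convention — Fab interfaces bury roughly 1500-1800 Å² summed over both
sides — so the half convention is the headline number, but since the
source of those figures does not name its convention, both are always
printed and the regression flags the one that matches.  Burial-based
footprints use a 1.0 Å² threshold on per-residue buried area; they are
deliberately kept distinct from contact-based footprints, and
cross-complex comparisons use the contact-based definition because the
published per-residue tables are contact-based.

## Cross-complex comparison

**Superposition.**  `kabsch_superpose()` is the standard SVD solution
with the determinant forced to +1: a reflection can never be the answer
for chiral molecules, even when it would lower the RMSD.  Collinear
point sets are rejected rather than silently returning one of the
infinitely many fits.  For cross-complex work the fit uses C-alpha atoms
of the alpha1-alpha2 platform (residues 1-180), paired by author number
— HLA allelomorphs share mature numbering, so sequence alignment is only
a fallback (`map_residues(mode = "by_alignment")`, global alignment with
match +1, mismatch -1, gap open -2, extend -1 under the affine
convention where a gap of length L costs open + L·extend).  A transplant
fit with fewer than 30 residue correspondences is refused as unreliable.

**Footprint overlap.**  Footprints from several complexes are mapped
onto the reference numbering (identity by default, explicit
correspondences otherwise; unmappable residues are listed, never
dropped) and intersected.  The overlap of the antibody with both KIRs is
computed with no segment restriction — the shared residues happen to lie
on the alpha2-1 helix — and the helix-restricted view is printed
alongside.  The Jaccard index |shared| / |union| summarizes each
comparison.

**Clash analysis.**  A transplanted receptor clashes with the reference
antibody where an atom pair's distance is below
`r_i + r_j - 0.4` Å — the 0.4 Å van der Waals overlap that the
MolProbity tradition calls a clash.  The source material says "clash"
without defining it, so the threshold is explicit, reported, and
adjustable (1.5 Å for severe-only scans).  Counts are binned by
(receptor domain × antibody domain); KIR domain ranges ship as an
editable fixture (`inst/extdata/kir_domain_segments.csv`, approximate
Ig-domain boundaries) with a midpoint split as the hint-free fallback
for two-domain receptors.

## SPR single-cycle kinetics

The 1:1 Langmuir surface-binding model is
`dR/dt = ka·C·(Rmax − R) − kd·R`.  Single-cycle kinetics injects an
increasing concentration series without regeneration; the response is
piecewise closed-form, each phase inheriting the previous phase's final
response, which the tests hold to a numerical ODE integration within
1e-6 RU and to continuity at every boundary.  The default schedule is
the five-injection, 2-fold series from 31.25 to 500 nM with 120 s
injection and dissociation phases — the protocol under which the
wild-type antibody/HLA affinity of this system was measured.

Fitting is global nonlinear least squares over the full trace in
`(log ka, log kd, Rmax, R0)`; the log parameterization keeps rates
positive without constrained optimization.  Identifiability guards
reject flat traces and single-concentration designs (with one
concentration, `ka` and `Rmax` trade off freely).  Sixteen multistarts
on a log-uniform grid (`ka` in 1e3-1e7 M⁻¹s⁻¹, `kd` in 1e-5-1e-1 s⁻¹)
cover the plausible kinetic space; the best converged restart wins, and
`KD = kd/ka` exactly.  Deliberately out of scope: mass-transport
limitation, baseline drift, bulk refractive-index jumps, and
heterogeneous-ligand models — the reference analysis fits a plain 1:1
model, and adding nuisance terms it did not use would change what the
recovered rates mean.  Reported affinities for this system (wild type
0.02 µM, peptide position-8 variants ~8-90 nM, the HLA-A*02:01 gain-of-
binding mutants, the 9.5-17 µM KIR range) ship as an annotation fixture
(`load_kd_fixtures()`) for contextualizing fit output; they are
literature values, never fit targets.

## Trajectory statistics

`rmsd_series()`, `rmsd_distribution()` and `rmsf()` are post-hoc
analyses of existing trajectories; no simulation engine, force field or
thermostat lives in this package, and binary MD formats are excluded on
purpose (multi-model PDB and a plain XYZ dialect keep the module free of
engine coupling — its accuracy is established on synthetic input).  The
RMSD distribution is a density-normalized histogram whose mean and SD
come from the raw series, not the bins.  RMSF uses a two-pass
alignment — fit to frame 1, compute the mean structure, re-fit to the
mean — because the reference for published RMSF profiles (first frame,
mean structure, or experimental model) is generally unstated; the
protocol is recorded in the output metadata instead of guessed.  A
residue's RMSF is the root mean squared fluctuation of its selected
atoms (backbone by default) about their mean positions; for isotropic
Gaussian jitter with per-coordinate standard deviation σ the expectation
is σ·√3, which is the calibration the recovery tests use.  Published MD
summary numbers for this system (e.g. an RMSD distribution of
2.96 ± 0.64 Å for the wild-type fragment) required the authors' 100 ns
trajectories, which are not deposited; the module's checks are therefore
property-based on synthetic trajectories rather than regressions against
those figures.

## What the synthetic generators emulate — and what they do not

`build_ideal_helix()` produces a canonical helix (rise 1.5 Å, twist
100°, C-alpha radius 2.3 Å, giving the ~3.8 Å consecutive C-alpha
spacing); with `backbone = TRUE` each residue carries alanine-like
N/CA/C/O/CB pseudo-atoms at fixed local offsets.  `build_toy_complex()`
places probe residues at exact designed distances from helix residues,
so the generator's placement table *is* the ground-truth contact table.
`gen_jitter_trajectory()` adds seeded, independent, isotropic Gaussian
displacements per residue, optionally wrapped in random global rigid
motions to exercise alignment.

These fixtures validate the geometry, bookkeeping and statistics of
every analysis stage, and that is all they validate.  They have no
side-chain rotamers, no Ramachandran-plausible backbones, no correlated
motions, no solvent.  Passing tests on them demonstrates that the
operators compute what they claim on inputs with known truth — not that
any particular biological complex has a particular buried area.  The
regression against the deposited models (`run_accession_regressions()`)
exists precisely to make that second kind of claim, and it runs only
when the user supplies the deposited coordinate files (the package never
downloads; see `?deposited_dir`).

## Numerical choices and problem sizes

* SASA: 960 lattice points, probe 1.4 Å, heavy atoms only.  Doubling
  the lattice changes per-atom values by under 2% on the fixtures.
* Contact and clash scans use a cell-list grid with the cutoff as cell
  edge; results are required to be identical to brute force.
* Kinetic fits: Levenberg-Marquardt (via `minpack.lm`), 300 iteration
  cap, 16 restarts; standard errors from the residual covariance at the
  optimum.
* The verification suite runs at desk scale, chosen as the smallest
  sizes at which the statistical checks are sharp: 100 seeds for the
  noisy K_D recovery study (median relative error compared against a 5%
  band), 2000 frames and 30 residues for RMSF calibration (5% on σ√3,
  rank correlation above 0.95 for amplitude-profile recovery), 5-degree
  rotation grids with local refinement for the superposition oracle.
* Degenerate inputs fail loudly and early: empty structures, collinear
  point sets, overlapping interface groups, flat sensorgrams,
  single-frame RMSF requests, and vanishing-occupancy traces all raise
  errors naming the problem.

## Known limitations

* Solvent-accessible area is not the molecular (solvent-excluded)
  surface; the two differ systematically, and published areas computed
  with other programs may differ by a few percent for that reason alone.
* Contact classification is distance-only; hydrogen-bond assignments in
  published tables produced with geometry-aware tools will not match
  record-for-record, though contact existence at 4.0 Å will.
* The role heuristic assumes one MHC complex per file; crystal forms
  with several copies in the asymmetric unit need chain hints to select
  a copy (symmetry expansion is out of scope).
* Cross-allelomorph residue mapping by author number silently assumes
  the deposited numbering is mature-protein numbering; files numbered
  from the initiator methionine need the alignment fallback.
* The 1:1 kinetic model cannot describe avidity or heterogeneous
  surfaces; fits to such data will converge but the rates will be
  effective, not microscopic.
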