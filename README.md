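# epiblock

Structural and biophysical analysis of antibody/MHC class I complexes
and their competition with inhibitory NK-cell receptors.

Monoclonal antibodies that bind a conserved surface of human MHC class I
(HLA-A/-B/-C) can sterically block the inhibitory killer
immunoglobulin-like receptors (KIR) that engage the same surface,
unleashing natural killer cells against tumors.  Establishing that
blocking mechanism from structures requires a reproducible chain of
computations — interface contacts and buried surface area, cross-complex
footprint overlap, receptor-transplant clash analysis, SPR binding
kinetics, and MD trajectory statistics.  `epiblock` packages that chain
for structural immunologists and antibody engineers, with seeded
synthetic generators so every stage is testable without external
coordinate files.

## What it computes

* **Interface contacts** — heavy-atom pairs within a cutoff (default
  4.0 Å) between chain groups with semantic roles (MHC heavy chain,
  β2-microglobulin, peptide, antibody H/L, receptor); closest-contact
  reduction per residue pair; contact maps; advisory hydrogen-bond /
  salt-bridge classification.
* **Buried surface area** — Shrake–Rupley SASA on a golden-spiral
  lattice with Chothia-type van der Waals radii and a 1.4 Å probe;
  BSA = SASA(A) + SASA(B) − SASA(AB), reported both as the two-side
  total and the per-interface half convention.
* **Footprint overlap** — epitope/paratope residue sets mapped across
  complexes on shared HLA mature numbering (Kabsch superposition of the
  α1–α2 platform, correspondence by author number or by sequence
  alignment), with multi-way shared/unique sets and Jaccard index.
* **Clash analysis** — a receptor transplanted from its own complex
  into the antibody complex clashes where atom pairs overlap their van
  der Waals radii by more than 0.4 Å; counts are binned by
  (receptor domain × antibody domain).
* **SPR single-cycle kinetics** — simulation and global nonlinear
  least-squares fitting of sensorgrams under the 1:1 Langmuir model
  `dR/dt = k_a·C·(R_max − R) − k_d·R`, chained across an
  increasing-concentration injection series; `K_D = k_d / k_a`.
* **Trajectory statistics** — aligned backbone RMSD series, the RMSD
  probability distribution P(d) with mean ± SD, and per-residue RMSF
  about the mean structure (two-pass alignment).

## Worked example

A toy complex with three designed contacts (3.2, 3.0, 3.6 Å from helix
residues 143, 146, 150) is generated, analyzed, and checked against its
own ground truth:

```r
library(epiblock)

toy <- build_toy_complex(placements = data.frame(
  target_resno = c(143, 146, 150), distance = c(3.2, 3.0, 3.6)))
rep <- interface_report(toy$model, toy$map)
rep$interface
#> Interface mhc_heavy / ab_light:
#>   BSA (total, both sides summed): 158.1 A^2
#>   BSA (half, per interface):      79.1 A^2
#>   burial per side: 77.2 / 80.9 A^2
#>   footprint residues (dSASA > 1 A^2): 6
rep$epitope
#>   chain resno ins resid n_contacts n_partners
#> 1     A   143       ALA          1          1
#> 2     A   146       ALA          1          1
#> 3     A   150       ALA          1          1
```

The epitope footprint is exactly the three designed residues, and the
buried area is reported under both conventions (the per-interface
number is what antibody/antigen papers usually quote).  Kinetics the
same way — simulate a single-cycle run at the standard 31.25→500 nM
2-fold series with 2 RU of noise, then fit it back:

```r
fit <- fit_sck(simulate_sck(sck_schedule(),
                            kinetic_params(ka = 1e5, kd = 2e-3, Rmax = 100),
                            noise_sd = 2, seed = 42))
fit
#> 1:1 single-cycle kinetic fit:
#>   ka   = 9.957e+04 1/(M s)
#>   kd   = 0.001991 1/s
#>   Rmax = 99.93 RU
#>   KD   = 2e-08 M (20 nM)
#>   RSS  = 4806 RU^2
```

The generating `K_D` of 20 nM is recovered from the noisy trace.  For
shell use, a thin wrapper over the same functions lives at
`inst/cli/epiblock.R` (subcommands `interface`, `compare`, `clash`,
`peptide`, `spr-simulate`, `spr-fit`, `synth-complex`, `synth-traj`).

## Documentation

The methods vignette (`vignettes/interface-analysis.Rmd`) documents the
models and their assumptions, every tunable parameter with units and
defaults, what the synthetic generators do and do not emulate, numerical
choices, and known limitations.
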