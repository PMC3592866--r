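# oligostate

Deciding whether a small protein domain is a monomer or a dimer in solution
is surprisingly hard when the domain is ~6 kDa: the folded dimer and the
unfolded monomer have nearly the same hydrodynamic size, and no folded
monomeric intermediate may exist at all. The dimerization elements of
STAR-family RNA-binding proteins (QUA1 domains, α-helical hairpins that
homodimerize) are the motivating case. The practical answer is to combine
several quantitative lines of evidence, and `oligostate` implements each of
them as tidy, pipe-friendly R functions:

* **SEC hydrodynamics** — column calibration on the
  `Mr^(1/3)` / `Rs` vs `(-log10 Kav)^(1/2)` axes (void volume fitted when
  unknown), apparent molecular weights, Stokes radii, apparent aggregation
  numbers (AAN), oligomeric-state calls, and dimer fractions of unresolved
  two-state mixtures via linear apex mixing:
  `f_dimer = (Rs_obs − Rs_mon)/(Rs_dim − Rs_mon)`.
  Reference predictors `log10(Rs/Å) = −0.204 + 0.357·log10(Mr)` (folded
  globular) and `−0.551 + 0.493·log10(Mr)` (unfolded) give the expected
  end-member radii from mass alone.
* **Structure geometry** — multi-model PDB ensembles as long atom tibbles;
  dihedral-based helix assignment; SVD helix axes; orientation-free
  inter-helix and protomer docking angles; Kabsch superposition and
  iterative mean-structure ensemble RMSD; Shrake–Rupley SASA; PISA-style
  per-protomer buried interface area; typed contacts (H-bonds, salt
  bridges, non-polar packing).
* **¹⁵N relaxation** — model-free rates, overall rotational correlation
  time by exact inversion of the rigid-rotor R2/R1 ratio
  (`τc ≈ (4πν_N)^(−1)·sqrt(6R2/R1 − 7)` as the classical shortcut),
  hetNOE-based structured-region delineation, MAD-rule exchange-broadening
  flags, amide shift dispersion, and a simple Cα/Cβ secondary-shift helix
  classifier.
* **Equilibrium models** — a two-state dimer melt `N2 ⇌ 2U` with van't Hoff
  `K(T) = Ct·exp[−(ΔH/R)(1/T − 1/Tm)]` and the midpoint convention
  `K(Tm) = Ct`, and single-species sedimentation equilibrium
  `c(r) = b + c_ref·exp[M(1−v̄ρ)ω²(r²−r_ref²)/(2RT)]` with a globally
  shared molar mass.
* **Synthetic data** — generators for every input class (chromatograms,
  ideal helical-hairpin dimers with controlled angles, relaxation tables,
  melts, radial profiles) with known ground truth, seed-reproducible.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and carry
`autoplot()` methods; reports (`sec_report()`, `structure_report()`)
aggregate the stages.

## Worked example: interpreting an SEC mutant series

The published characterization of the pXqua QUA1 domain ran
maltose-binding-protein fusions of the domain and its interface mutants on
a 2.41 mL analytical column. Calibrating from the reported standards and
interpreting each construct's elution volume:

```r
library(oligostate)
library(tibble)

standards <- tibble(ve_ml = c(1.27, 1.40, 1.42, 1.57),
                    mr_da = c(234e3, 131e3, 120e3, NA),
                    rs_angstrom = c(54, 44, 42, 32))
cal <- fit_sec_calibration(standards, vt_ml = 2.41)
cal
#> <sec_calibration>
#>   column: Vo = 0.845 mL (fitted), Vt = 2.41 mL
#>   Mr^(1/3) line: intercept -38.157, slope 132.649 (Da^1/3)
#>   Rs line: intercept -41.11, slope 126.48 (Angstrom)
#>   calibration domain: 1.27-1.57 mL (4 standards)

samples <- tibble(
  sample = c("wild-type (peak 1)", "wild-type (peak 2)", "C59S",
             "C59S/E72G", "C59S/R67A", "C59S/R67E/E72R"),
  ve_ml = c(1.27, 1.42, 1.40, 1.57, 1.50, 1.46))
sec_report(samples, cal, monomer_mass_da = 48000,
           rs_monomer = 32, rs_dimer = 44)
#>   sample             ve_ml   kav amw_da rs_angstrom   aan state         dimer_fraction
#> 1 wild-type (peak 1)  1.27 0.272 233948        54     4.9 higher-order            1
#> 2 wild-type (peak 2)  1.42 0.368 119766        42.3   2.5 dimer                   0.86
#> 3 C59S                1.40 0.355 131284        43.7   2.7 dimer                   0.98
#> 4 C59S/E72G           1.57 0.463  57096        32     1.2 monomer                 0
#> 5 C59S/R67A           1.50 0.419  81786        36.7   1.7 monomer/dimer           0.39
#> 6 C59S/R67E/E72R      1.46 0.393  99286        39.4   2.1 monomer/dimer           0.62
```

Reading the table: the wild-type protein runs as a disulfide-linked
tetramer plus a dimer; the cysteine-free C59S construct is a clean dimer
(AAN 2.7 — elongated fusion dimers run above 2 on a globular calibration);
the E72G interface mutant is a pure monomer at the 32 Å unfolded-monomer
end member; and the R67A and R67E/E72R interface mutants are unresolved
mixtures whose apex positions put ~39% and ~62% of the protein in the
dimeric state.

A relaxation table simulated at the published tumbling regime shows the
other half of the workflow:

```r
tab <- simulate_relaxation(55, tau_c_ns = 9.9, field_mhz = 500,
                           flexible_termini = 8, noise_fraction = 0.02,
                           seed = 42)
glance(estimate_tau_c(tab))
#>   tau_c_ns sd_ns n_used n_rejected field_mhz method
#> 1     9.95 0.191     38         17       500 exact
structured_region(tab)
#>   first_residue last_residue n_residues
#> 1             9           47         39
```

A correlation time near 10 ns at 500 MHz is what a ~12 kDa species should
show — direct evidence for a tumbling dimer rather than a 6 kDa monomer —
and the hetNOE profile delineates a 39-residue structured core flanked by
flexible tails.

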