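---
title: "Methods: inferring the oligomeric state of a small dimerization domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring the oligomeric state of a small dimerization domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligostate)
library(tibble)
```

Small dimerization elements — the QUA1 domain of STAR-family RNA-binding
proteins is the motivating case — are awkward objects: the folded dimer and
the unfolded monomer of a ~6 kDa domain have nearly the same hydrodynamic
size, no folded monomeric intermediate exists, and the interface is small
enough that single point mutations flip the equilibrium. Establishing that
such a domain is an α-helical-hairpin homodimer therefore rests on several
independent lines of evidence, each quantitative but none decisive alone.
`oligostate` implements those lines as one composable toolkit: analytical
size-exclusion chromatography (SEC), ensemble structure geometry, backbone
¹⁵N relaxation, and two equilibrium models. A synthetic-data layer generates
every input class with known ground truth, so each estimator ships with
parameter-recovery tests that run offline.

## SEC hydrodynamics

A species eluting at volume $V_e$ on a column of void volume $V_o$ and total
volume $V_t$ has partition coefficient

$$K_{av} = \frac{V_e - V_o}{V_t - V_o}.$$

Two linear calibrations share the abscissa $x = (-\log_{10} K_{av})^{1/2}$:
apparent molecular weight via $M_r^{1/3} = a + b\,x$, and apparent Stokes
radius via $R_S = a' + b'\,x$. Both are ordinary least squares on the
transformed axes (`fit_sec_calibration()`), with the calibration domain
recorded and extrapolation flagged.

Column data sheets rarely state $V_o$ for analytical columns, so when it is
not supplied it is treated as a fit parameter: a fine 1-D scan over
$[0.3\,V_t,\ 0.6\,V_t]$ (capped just below the earliest standard) with an
inner linear fit, picking the void volume that minimizes the summed squared
residuals, each line normalized by its response variance so that mass and
radius standards can be mixed. On the four-standard radius calibration used
in the worked example the scan has a well-defined interior optimum near
$0.35\,V_t$, and on the three-standard mass calibration near $0.41\,V_t$ —
physically sensible values for a packed gel-filtration column.

Two empirical predictors give reference Stokes radii from mass alone:
$\log_{10}(R_S/\text{Å}) = -0.204 + 0.357\,\log_{10}(M_r/\text{Da})$ for
folded globular chains and $-0.551 + 0.493\,\log_{10}(M_r)$ for unfolded
chains. Note the exponents differ, so the two lines cross near 360 Da; the
"folded is more compact" ordering holds over the protein mass range, which
is what the invariant tests assert.

The apparent aggregation number AAN = AMW / monomer mass is deliberately
crude — elongated fusion dimers run large on a globular calibration — so the
state classifier uses wide half-open bands (monomer < 1.35 ≤ monomer/dimer
< 2.25 ≤ dimer < 3.6 ≤ higher-order). These edges are configurable; the
defaults reproduce the standard interpretation of maltose-binding-protein
fusion constructs, where a clean dimer shows AAN ≈ 2.4–2.8.

For an unresolved two-state mixture the single apex is assumed to move
linearly between end-member positions, and the dimer fraction is computed in
radius space, $(R_{S,obs} - R_{S,mon})/(R_{S,dim} - R_{S,mon})$, clipped to
$[0,1]$ with a warning. The linear-apex assumption is only sensible when the
envelope is genuinely unimodal; with peak widths much narrower than the
separation the envelope is bimodal and `detect_peaks()` (local maxima plus
three-point parabolic apex refinement) will correctly report two peaks
instead.

## Structure geometry

Ensembles are long atom tibbles (one row per atom per model) read and
written through multi-model PDB (`read_structure()` / `write_structure()`,
bio3d underneath). Helices are assigned from backbone dihedrals: residues
with $\phi \in [-100, -30]$, $\psi \in [-67, -7]$ in runs of ≥ 4, bridging
single-residue gaps but never bridging breaks in the author numbering.
Helix axes are the principal SVD direction of the segment's Cα cloud,
oriented N→C; for 14–17-residue helices this recovers generator ground
truth to well under a degree, and the perpendicular residual (`fit_rms`)
lands on the ~2.3 Å Cα cylinder radius.

Crossing angles are reported orientation-free, $\min(\theta, 180 - \theta)$.
The **docking angle** between two hairpin protomers needs an axis definition
for a two-helix object; we use the principal direction of the
length-weighted bundle of helix-axis outer products
$\sum_i n_i\, \hat a_i \hat a_i^\top$. For an antiparallel hairpin this is
the orientation-free mean helix direction. The more obvious choice — the
principal component of all helical Cα coordinates — becomes nearly
degenerate with the inter-helix offset direction once helices are short
(the two leading eigenvalues cross near 12 residues/helix at 9.5 Å axis
separation), and then flips under coordinate noise; the bundle definition
has no such degeneracy for crossing angles below 90°. Angles are computed
per model and reported mean ± sd across the ensemble.

Ensemble precision follows the usual NMR convention: all models are
iteratively superposed (Kabsch SVD superposition with proper rotation
enforced) onto the evolving mean structure until the mean moves by less
than $10^{-4}$ Å, then the per-model RMSD to the mean is summarized as
mean ± sd.

SASA is Shrake–Rupley with Bondi radii, a 1.4 Å probe and a deterministic
960-point golden-spiral sphere sampling; hydrogens are excluded by default
so NMR ensembles (which carry protons) are comparable with heavy-atom
conventions. Buried interface area is $(\mathrm{SASA}_A + \mathrm{SASA}_B -
\mathrm{SASA}_{AB})/2$ — the per-protomer value quoted by interface servers —
with the unhalved total reported alongside. Per-residue relative exposure
normalizes against the same residue's atoms extracted and recomputed in
isolation. This self-reference convention (rather than a Gly-X-Gly
tripeptide table) needs no side-chain rebuilding, makes an isolated residue
score exactly 1, and is computed by the same SASA engine, so numerator and
denominator share sampling bias.

Contacts use heavy-atom criteria: hydrogen bonds at donor–acceptor ≤ 3.5 Å
with an antecedent–donor–acceptor angle ≥ 90°; salt bridges at ≤ 4.0 Å
between Asp/Glu carboxylate oxygens and Lys/Arg/His side-chain nitrogens;
non-polar packing at C–C ≤ 4.5 Å between apolar side chains, one contact
per residue pair at the closest atom pair, each tagged intra/inter-protomer.

## ¹⁵N relaxation

Rates come from the standard dipolar + CSA spectral densities under the
Lipari–Szabo model-free form with isotropic tumbling,

$$J(\omega) = \tfrac{2}{5}\left[\frac{S^2 \tau_c}{1 + (\omega\tau_c)^2}
  + \frac{(1 - S^2)\,\tau'}{1 + (\omega\tau')^2}\right],
  \qquad \tau'^{-1} = \tau_c^{-1} + \tau_e^{-1},$$

with N–H bond length 1.02 Å, ¹⁵N CSA −160 ppm, and standard gyromagnetic
ratios. These constants live in `relaxation_constants()` and are shared by
the generator and the estimator, so consistency — which matters more than
the precise values — is structural.

The overall correlation time uses only residues that report on overall
tumbling: hetNOE ≥ 0.65 *and* R2 within 1.5 MAD of the retained-set median
(the first cut removes flexible residues, the second exchange-broadened
ones; a small tolerance keeps perfectly homogeneous noiseless cores intact
when the MAD collapses to zero). Each surviving R2/R1 ratio is then
inverted to a per-residue $\tau_c$. The familiar closed form
$\tau_c = (4\pi\nu_N)^{-1}\sqrt{6 R_2/R_1 - 7}$ is a large-$\tau_c$
approximation that is biased by 1–2% at 5–20 ns and 500–800 MHz; since the
exact rigid-rotor ratio curve is monotone, we root-find on it instead
(`method = "exact"`, the default), using the closed form as the bracket
centre. The closed form remains available as `method = "approx"`. The
estimate is a 10%-trimmed mean ± sd. Residues with $6R_2/R_1 \le 7$ tumble
too fast to carry the information and are rejected, not fatal.

Structured regions are maximal runs (≥ 5 residues) with hetNOE ≥ 0.65,
tolerating single-residue dips. Exchange broadening is flagged as R2
exceeding the structured-region median by > 3 MAD. Shift dispersion is the
max–min of backbone amide ¹H shifts; a folded domain shows several ppm
where a random coil stays under ~0.8. The secondary-shift classifier is a
deliberately simple stand-in for dihedral-prediction software: smoothed
(3-residue window) $\Delta\delta C_\alpha - \Delta\delta C_\beta$ against a
Wishart-style random-coil table, helix where ≥ +1.4 ppm in runs of ≥ 4.

## Equilibrium models

**Thermal unfolding.** The melt model couples unfolding to dissociation,
$N_2 \rightleftharpoons 2U$, with van't Hoff temperature dependence and the
midpoint convention $K(T_m) = C_t$ so that exactly half the monomer units
are unfolded at $T_m$ *at the stated total monomer concentration* — dimer
melts are concentration-dependent, so a $T_m$ quoted without $C_t$ is
ambiguous. $\Delta C_p$ is fixed at 0 (the data being emulated constrain
only $T_m$). The observed signal interpolates two linear baselines weighted
by the unfolded fraction, which is the positive quadratic root written in
conjugate form to avoid cancellation at small $K$. Fitting is
Levenberg–Marquardt least squares; initialization takes baselines from the
terminal 10% of points, $T_m$ from the extremum of a smoothed derivative
(window scaled to the grid, edges excluded, noise gauged on the baseline
quarters so the transition cannot inflate its own detection threshold), and
$\Delta H$ from the transition width.

**Sedimentation equilibrium.** A single ideal species at equilibrium gives
$c(r) = b + c_{ref}\exp[\sigma (r^2 - r_{ref}^2)/2]$ with
$\sigma = M(1 - \bar v \rho)\,\omega^2 / (RT)$. The global fit shares one
molar mass across profiles with per-profile baseline and reference
concentration (kept positive by parameterizing its logarithm), initialized
from the linearized $\ln(c - b)$ vs $r^2/2$ regression. The rotor speeds,
partial specific volume and solvent density are inputs, not fits; the
defaults ($\bar v = 0.73$ mL/g, $\rho = 1.0$ g/mL, 20 and 28 krpm, 293 K)
are ordinary values for an aqueous protein experiment and must be replaced
with the actual experimental values when reanalyzing real data.

## What the synthetic data do and do not emulate

The generators produce: Gaussian elution peaks (including unresolved
two-state mixtures) with additive Gaussian noise; ideal backbone-only
(N, Cα, C, O) helical hairpins built from internal coordinates
(φ = −60°, ψ = −45°, ideal bond geometry) with exact control of the
inter-helix and docking angles and a clash-free inter-protomer gap;
isotropic-tumbling relaxation profiles whose flexible termini ramp the
order parameter down to 0.2 with a 1 ns internal correlation time
(residues that consequently fall below the 0.65 NOE cutoff, as disordered
tails do); two-state dimer melts; and exponential radial distributions.
All are exact evaluations of their closed forms at zero noise, and
bit-reproducible given a seed.

They do **not** emulate chromatographic tailing or column non-ideality,
side chains (buried areas of the backbone-only fixtures are far smaller
than for real interfaces, so interface assertions on synthetic data are
property-level: additivity bounds, gap monotonicity), anisotropic
diffusion, CSA/dipolar cross-correlation, or thermodynamic baselines with
curvature. Passing the recovery tests therefore demonstrates correctness of
the estimators under their stated models, not robustness to every artifact
of real data.

Default study conditions used by the recovery tests: $\tau_c$ = 9.9 ns at
500 MHz with a 39-residue structured core; melts with
$\Delta H$ = 300 kJ/mol, $T_m$ = 338.15 K at $C_t$ = 20 µM over
293–368 K in 0.5 K steps with ~1% noise; sedimentation of a 12.3 kDa
species at 0.5% noise over 80 radial points per speed; hairpin recovery
across 0–90° angle grids with 14 residues per helix. Replicate counts (50
seeds for the stochastic recoveries, 25 for exchange-flag misses, 200 for
the false-positive rate) keep the whole suite under a minute while making
the asserted tolerances (2–5% on $\tau_c$, 0.5 K on $T_m$, 2% on molar
mass, 1–2° on angles) statistically meaningful.

## Numerical choices and degenerate inputs

* $K_{av}$ slightly outside $[0,1]$ from apex-interpolation jitter is
  clamped with a warning; standards, however, must elute strictly inside
  the column volume.
* Calibration fits with a single distinct $K_{av}$ raise a singular-fit
  error; negative predicted $M_r^{1/3}$ or $R_S$ raise range errors rather
  than returning nonsense.
* Superposition enforces a proper rotation (determinant +1) and rejects
  collapsed point sets; ensemble superposition iterates at most 100 times
  with a $10^{-4}$ Å mean-coordinate tolerance.
* SASA point counts trade accuracy for time: 960 points give ~1% accuracy
  on isolated spheres and ~2% against a dense latitude-band oracle on
  two-atom toys. Unknown elements get a configurable default radius with a
  warning.
* The hairpin generator verifies the requested inter-protomer gap by
  bisection on the packing translation; an explicit `protomer_offset` that
  violates the gap is rejected as impossible geometry.
* Exchange-site exclusion and flagging use MAD-based bands with a tiny
  absolute tolerance so that noiseless (zero-MAD) tables behave sensibly.

## Known limitations

* SEC interpretation assumes the linear calibration holds across the run;
  strongly non-globular species violate the mass line (which is precisely
  why the aggregation-number bands are wide).
* The ~linear apex interpolation for mixtures is a crude estimator by
  construction; treat fractions as order-of-magnitude statements.
* The relaxation analysis is single-field R2/R1 inversion; no model-free
  fitting of $S^2$/$\tau_e$, no anisotropic diffusion tensors, no RDC
  analysis.
* The melt model offers no $\Delta C_p$ and no folded-monomer intermediate;
  the sedimentation model is single-species and ideal.
* Deposited-data workflows (`fetch_pdb()`, `fetch_bmrb_shifts()`) are
  explicit network operations; everything else, including the full test
  suite, runs offline.
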