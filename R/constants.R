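# Shared physical constants and lookup tables. The relaxation constants are
# deliberately exposed through relaxation_constants() so that the synthetic
# generator and the tau_c estimator are guaranteed to use the same values.

#' Physical constants used in the 15N relaxation model
#'
#' Returns the constants entering the dipolar/CSA spectral-density
#' expressions for a backbone amide 15N spin: gyromagnetic ratios of 1H and
#' 15N, the N-H bond length, and the 15N chemical-shift anisotropy. The
#' synthetic relaxation generator ([simulate_relaxation()]) and the
#' correlation-time estimator ([estimate_tau_c()]) both draw on this single
#' set, so parameter-recovery round trips are exact by construction.
#'
#' @return A named list: `gamma_h` and `gamma_n` (rad s^-1 T^-1), `r_nh` (m),
#'   `csa` (dimensionless, -160 ppm), `mu0` (T m A^-1) and `hbar` (J s).
#' @export
#' @examples
#' relaxation_constants()$csa
relaxation_constants <- function() {
  list(
    gamma_h = 2.6752218744e8,
    gamma_n = -2.71261804e7,
    r_nh    = 1.02e-10,
    csa     = -160e-6,
    mu0     = 4e-7 * pi,
    hbar    = 1.054571817e-34
  )
}

# Gas constant, J mol^-1 K^-1
.R_gas <- 8.31446261815324

# Bondi van der Waals radii (Angstrom) by element symbol.
.vdw_bondi <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

#' Van der Waals radii used for surface-area calculations
#'
#' The Bondi radius set, keyed by element symbol. [sasa()] falls back to a
#' configurable default (with a warning) for elements missing from the table.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() .vdw_bondi

# Random-coil 13CA / 13CB chemical shifts (ppm), Wishart-style reference set,
# used by classify_secondary_shifts().
.random_coil_shifts <- tibble::tibble(
  resname = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL"),
  ca = c(52.5, 56.0, 53.1, 54.2, 58.2, 55.7, 56.6, 45.1, 55.0,
         61.1, 55.1, 56.2, 55.4, 57.7, 63.3, 58.3, 61.8, 57.5,
         57.9, 62.2),
  cb = c(19.1, 30.9, 38.9, 41.1, 28.0, 29.4, 29.9, NA, 29.0,
         38.8, 42.4, 33.1, 32.9, 39.6, 32.1, 63.8, 69.8, 29.6,
         38.8, 32.9)
)

#' Random-coil carbon shift reference table
#'
#' Random-coil 13CA and 13CB chemical shifts for the twenty standard amino
#' acids (Wishart-style reference values), used to form secondary shifts in
#' [classify_secondary_shifts()].
#'
#' @return A tibble with columns `resname`, `ca`, `cb` (ppm).
#' @export
random_coil_shifts <- function() .random_coil_shifts

# --- hydrogen-bond chemistry tables (heavy-atom criteria) ------------------

# donor atoms: (resname-or-"*" , atom, antecedent)
.hb_donors <- tibble::tribble(
  ~resname, ~atom,  ~antecedent,
  "*",      "N",    "CA",
  "SER",    "OG",   "CB",
  "THR",    "OG1",  "CB",
  "TYR",    "OH",   "CZ",
  "ASN",    "ND2",  "CG",
  "GLN",    "NE2",  "CD",
  "LYS",    "NZ",   "CE",
  "ARG",    "NE",   "CD",
  "ARG",    "NH1",  "CZ",
  "ARG",    "NH2",  "CZ",
  "HIS",    "ND1",  "CG",
  "HIS",    "NE2",  "CD2",
  "TRP",    "NE1",  "CD1"
)

# acceptor atoms: resname "*" means any residue type
.hb_acceptors <- tibble::tribble(
  ~resname, ~atom,
  "*",      "O",
  "*",      "OXT",
  "ASP",    "OD1",
  "ASP",    "OD2",
  "GLU",    "OE1",
  "GLU",    "OE2",
  "ASN",    "OD1",
  "GLN",    "OE1",
  "SER",    "OG",
  "THR",    "OG1",
  "TYR",    "OH",
  "HIS",    "ND1",
  "HIS",    "NE2",
  "MET",    "SD"
)

# charged-group atoms for salt bridges
.sb_negative <- tibble::tribble(
  ~resname, ~atom,
  "ASP", "OD1", "ASP", "OD2",
  "GLU", "OE1", "GLU", "OE2"
)
.sb_positive <- tibble::tribble(
  ~resname, ~atom,
  "LYS", "NZ",
  "ARG", "NE", "ARG", "NH1", "ARG", "NH2",
  "HIS", "ND1", "HIS", "NE2"
)

# residues counted as apolar for nonpolar-contact detection
.apolar_residues <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

# backbone atom names
.backbone_atoms <- c("N", "CA", "C", "O")
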