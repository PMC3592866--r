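# Thin readers for the delimited-text schemas the package consumes.

#' Read a chromatogram CSV
#'
#' Expects columns `volume_ml` and `a280`.
#'
#' @param path CSV path.
#' @return Tibble ready for [detect_peaks()] / [plot_chromatogram()].
#' @export
read_chromatogram <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("volume_ml", "a280") %in% names(d))) {
    rlang::abort("Chromatogram CSV needs columns volume_ml, a280.")
  }
  d
}

#' Read SEC calibration standards from CSV
#'
#' Expects `ve_ml` plus at least one of `mr_da` and `rs_angstrom`; an
#' optional `name` column is carried through.
#'
#' @param path CSV path.
#' @return Tibble ready for [fit_sec_calibration()].
#' @export
read_sec_standards <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!"ve_ml" %in% names(d) ||
      !any(c("mr_da", "rs_angstrom") %in% names(d))) {
    rlang::abort("Standards CSV needs ve_ml and mr_da and/or rs_angstrom.")
  }
  d
}

#' Read a per-residue relaxation table from CSV
#'
#' Expects `residue`, `r1`, `r2` and optionally `noe`. The spectrometer
#' 1H frequency is not part of the schema; pass it to [estimate_tau_c()]
#' or set it via the `field_mhz` argument here.
#'
#' @param path CSV path.
#' @param field_mhz Optional 1H frequency stored as an attribute.
#' @return Relaxation tibble.
#' @export
read_relaxation_table <- function(path, field_mhz = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("residue", "r1", "r2") %in% names(d))) {
    rlang::abort("Relaxation CSV needs columns residue, r1, r2.")
  }
  if (!is.null(field_mhz)) attr(d, "field_mhz") <- field_mhz
  d
}

#' Read a chemical-shift table from CSV
#'
#' Expects `residue`, `atom`, `ppm` and optionally `resname`.
#'
#' @param path CSV path.
#' @return Shift tibble for [shift_dispersion()] /
#'   [classify_secondary_shifts()].
#' @export
read_shift_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("residue", "atom", "ppm") %in% names(d))) {
    rlang::abort("Shift CSV needs columns residue, atom, ppm.")
  }
  d
}
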