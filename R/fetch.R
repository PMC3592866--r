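# Explicit, opt-in retrieval of deposited data. Nothing in the package
# downloads implicitly; analyses and tests otherwise run entirely offline.

#' Download a deposited coordinate ensemble from the wwPDB
#'
#' Fetches `<id>.pdb` from the RCSB download service and reads it with
#' [read_structure()]. This is an explicit network operation.
#'
#' @param id 4-character PDB identifier (e.g. `"2YMJ"`).
#' @param dest Optional path to keep the downloaded file; defaults to a
#'   temporary file.
#' @return Atom tibble; see [read_structure()].
#' @export
fetch_pdb <- function(id, dest = NULL) {
  if (!grepl("^[0-9][A-Za-z0-9]{3}$", id)) {
    rlang::abort("`id` must be a 4-character PDB code.")
  }
  dest <- dest %||% tempfile(fileext = ".pdb")
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  ok <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
    error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    rlang::abort(sprintf(
      "Could not download %s from the wwPDB (offline?). Tried: %s", id, url))
  }
  read_structure(dest)
}

#' Download assigned chemical shifts from the BMRB
#'
#' Fetches the NMR-STAR 3.1 file for a BMRB entry and extracts the assigned
#' chemical-shift loop with [read_nmrstar_shifts()]. This is an explicit
#' network operation.
#'
#' @param entry BMRB accession number (e.g. `18782`).
#' @param dest Optional path to keep the downloaded file.
#' @return Tibble with columns `residue`, `resname`, `atom`, `ppm`.
#' @export
fetch_bmrb_shifts <- function(entry, dest = NULL) {
  entry <- as.integer(entry)
  dest <- dest %||% tempfile(fileext = ".str")
  url <- sprintf(
    "https://bmrb.io/ftp/pub/bmrb/entry_directories/bmr%d/bmr%d_3.str",
    entry, entry)
  ok <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
    error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    rlang::abort(sprintf(
      "Could not download BMRB entry %d (offline?). Tried: %s", entry, url))
  }
  read_nmrstar_shifts(dest)
}
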