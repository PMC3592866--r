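# Multi-model coordinate I/O. Ensembles are represented as long atom
# tibbles (one row per atom per model), the natural shape for dplyr-style
# selection; bio3d does the PDB parsing.

#' Read a (multi-model) PDB file into an atom tibble
#'
#' Loads every MODEL block of a PDB file, preserving author residue
#' numbering, and returns a long tibble with one row per atom per model.
#' All models must share an identical atom topology.
#'
#' @param path Path to a PDB file.
#' @return Tibble with columns `model`, `chain`, `resno`, `resname`,
#'   `atom` (PDB atom name), `element`, `x`, `y`, `z` (Angstrom).
#' @seealso [write_structure()]
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("No such file: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      rlang::abort(sprintf("Failed to parse PDB file '%s': %s", path,
                           conditionMessage(e)))
    })
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- nrow(at)
  n_models <- nrow(xyz)
  if (ncol(xyz) != 3 * n_atoms) {
    rlang::abort(sprintf(
      "Model topology mismatch: %d atoms in the header model but %d coordinates per MODEL block.",
      n_atoms, ncol(xyz) / 3))
  }
  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(gsub("[0-9]", "", at$elety), 1, 1),
                         at$elesy))
  per_model <- function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    tibble::tibble(
      model = m,
      chain = at$chain,
      resno = at$resno,
      resname = at$resid,
      atom = at$elety,
      element = elem,
      x = co[, 1], y = co[, 2], z = co[, 3]
    )
  }
  out <- dplyr::bind_rows(lapply(seq_len(n_models), per_model))
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    rlang::abort("Non-finite coordinates in structure.")
  }
  out
}

#' Write an atom tibble as a multi-model PDB file
#'
#' @param struct Atom tibble as returned by [read_structure()] or
#'   [simulate_hairpin_dimer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  struct <- .validate_struct(struct)
  models <- sort(unique(struct$model))
  first <- struct[struct$model == models[1], ]
  xyz <- do.call(rbind, lapply(models, function(m) {
    d <- struct[struct$model == m, ]
    if (nrow(d) != nrow(first)) {
      rlang::abort("Models differ in atom count; cannot write ensemble.")
    }
    as.numeric(t(as.matrix(d[, c("x", "y", "z")])))
  }))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = first$resno, resid = first$resname,
    eleno = seq_len(nrow(first)), elety = first$atom,
    chain = first$chain, elesy = first$element
  )
  invisible(path)
}

.validate_struct <- function(struct) {
  struct <- tibble::as_tibble(struct)
  need <- c("model", "chain", "resno", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(struct))) {
    rlang::abort(paste("Structure tibble needs columns:",
                       paste(need, collapse = ", ")))
  }
  if (!"element" %in% names(struct)) {
    struct$element <- toupper(substr(gsub("[0-9]", "", struct$atom), 1, 1))
  }
  struct
}

# coordinate matrix for one model (optionally one chain / atom subset)
.model_coords <- function(struct, model = 1, chain = NULL, atoms = NULL,
                          resno = NULL) {
  d <- struct[struct$model == model, ]
  if (!is.null(chain)) d <- d[d$chain %in% chain, ]
  if (!is.null(atoms)) d <- d[d$atom %in% atoms, ]
  if (!is.null(resno)) d <- d[d$resno %in% resno, ]
  as.matrix(d[, c("x", "y", "z")])
}
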