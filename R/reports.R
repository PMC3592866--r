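# Report builders tying the stages together: a Table-1-style SEC state
# table and a one-stop structure-geometry report.

#' SEC interpretation report
#'
#' Converts a table of sample elution volumes into the standard SEC
#' interpretation table: partition coefficient, apparent molecular weight,
#' apparent Stokes radius (when the calibration carries an Rs line),
#' aggregation number, oligomeric-state call, and — when end-member radii
#' are supplied — the mixture dimer fraction.
#'
#' @param samples Data frame with columns `sample` and `ve_ml` (one row per
#'   elution peak; repeated sample names are fine).
#' @param calibration A [fit_sec_calibration()] object.
#' @param monomer_mass_da Monomer molar mass used for aggregation numbers.
#' @param rs_monomer,rs_dimer Optional end-member Stokes radii (Angstrom)
#'   enabling the `dimer_fraction` column.
#' @param bands Oligomer classification band edges; see
#'   [classify_oligomer()].
#' @return Tibble with one row per peak: `sample`, `ve_ml`, `kav`, `amw_da`,
#'   `rs_angstrom` (if available), `aan`, `state`, `dimer_fraction` (if
#'   end-member radii were given).
#' @export
#' @examples
#' std <- tibble::tibble(ve_ml = c(1.27, 1.40, 1.42),
#'                       mr_da = c(234000, 131000, 120000))
#' cal <- fit_sec_calibration(std, vt_ml = 2.41)
#' sec_report(tibble::tibble(sample = "C59S", ve_ml = 1.40), cal, 48000)
sec_report <- function(samples, calibration, monomer_mass_da,
                       rs_monomer = NULL, rs_dimer = NULL,
                       bands = c(1.35, 2.25, 3.6)) {
  if (!inherits(calibration, "sec_calibration")) {
    rlang::abort("`calibration` must come from fit_sec_calibration().")
  }
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample", "ve_ml") %in% names(samples))) {
    rlang::abort("`samples` needs columns sample and ve_ml.")
  }
  out <- samples
  if (nrow(out) == 0) {
    out$kav <- numeric(); out$amw_da <- numeric(); out$aan <- numeric()
    out$state <- factor(levels = levels(classify_oligomer(1)))
    return(out)
  }
  out$kav <- compute_kav(out$ve_ml, calibration$vo_ml, calibration$vt_ml)
  out$amw_da <- estimate_amw(calibration, out$ve_ml)
  has_rs <- !is.null(calibration$rs_fit)
  if (has_rs) out$rs_angstrom <- estimate_rs(calibration, out$ve_ml)
  out$aan <- compute_aan(out$amw_da, monomer_mass_da)
  out$state <- classify_oligomer(out$aan, bands = bands)
  if (!is.null(rs_monomer) && !is.null(rs_dimer)) {
    if (!has_rs) {
      rlang::warn("No Rs calibration line; dimer_fraction column omitted.")
    } else {
      out$dimer_fraction <- estimate_dimer_fraction(
        out$rs_angstrom, rs_monomer = rs_monomer, rs_dimer = rs_dimer)
    }
  }
  out
}

#' Structure-geometry report for an ensemble
#'
#' Aggregates the geometric characterization of a (multi-model) two-chain
#' ensemble: helix segments, the within-protomer inter-helix crossing angle
#' and the protomer docking angle (per model, reported mean +/- sd),
#' ensemble coordinate precision (backbone and heavy, whole dimer), buried
#' interface area, and the inter-protomer contact list of the first model.
#'
#' @param struct Atom tibble.
#' @param chains Length-2 chain selection (default: first two chains).
#' @param residues Optional residue range for the RMSD statistics.
#' @param buried_models Models over which the buried area is averaged
#'   (default: all).
#' @return A list of class `structure_report` with elements `helices`,
#'   `angles`, `rmsd`, `interface` and `contacts`.
#' @export
structure_report <- function(struct, chains = NULL, residues = NULL,
                             buried_models = NULL) {
  struct <- .validate_struct(struct)
  models <- sort(unique(struct$model))
  present <- sort(unique(struct$chain))
  two_chains <- length(present) >= 2
  if (is.null(chains)) chains <- utils::head(present, 2)

  helices <- assign_helices(struct, model = models[1])

  interhelix <- vapply(models, function(m) {
    segs <- assign_helices(struct, model = m, chain = chains[1])
    segs <- segs[segs$n_residues >= 6, ]
    if (nrow(segs) < 2) return(NA_real_)
    crossing_angle(segs$axis[[1]], segs$axis[[2]])
  }, numeric(1))

  docking <- if (two_chains) {
    vapply(models, function(m) docking_angle(struct, model = m,
                                             chains = chains), numeric(1))
  } else NA_real_

  angles <- tibble::tibble(
    quantity = c("interhelix_angle", "docking_angle"),
    mean_deg = c(mean(interhelix, na.rm = TRUE), mean(docking, na.rm = TRUE)),
    sd_deg = c(sd(interhelix, na.rm = TRUE), sd(docking, na.rm = TRUE)),
    n_models = length(models)
  )

  rmsd <- if (length(models) >= 2) {
    dplyr::bind_rows(
      dplyr::mutate(ensemble_rmsd(struct, residues = residues,
                                  mode = "backbone"), mode = "backbone"),
      dplyr::mutate(ensemble_rmsd(struct, residues = residues,
                                  mode = "heavy"), mode = "heavy")
    )
  } else {
    rlang::warn("Single-model input; RMSD section skipped.")
    NULL
  }

  interface <- NULL
  contacts <- NULL
  if (two_chains) {
    bm <- buried_models %||% models
    per_model <- dplyr::bind_rows(lapply(bm, function(m) {
      buried_interface_area(struct, model = m, chain_a = chains[1],
                            chain_b = chains[2])
    }))
    interface <- tibble::tibble(
      buried_area_mean = mean(per_model$buried_area),
      buried_area_sd = sd(per_model$buried_area),
      n_models = nrow(per_model)
    )
    contacts <- find_contacts(struct, model = models[1])
  } else {
    rlang::warn("Single chain; interface section skipped.")
  }

  structure(list(helices = helices, angles = angles, rmsd = rmsd,
                 interface = interface, contacts = contacts),
            class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat("<structure_report>\n")
  cat("helices (model 1):\n")
  print(dplyr::select(x$helices, -dplyr::any_of(c("axis", "centroid"))))
  cat("angles over ensemble:\n"); print(x$angles)
  if (!is.null(x$rmsd)) { cat("coordinate precision:\n"); print(x$rmsd) }
  if (!is.null(x$interface)) {
    cat("interface:\n"); print(x$interface)
    cat(sprintf("contacts (model 1): %d (%d inter-protomer)\n",
                nrow(x$contacts), sum(x$contacts$span == "inter")))
  }
  invisible(x)
}
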