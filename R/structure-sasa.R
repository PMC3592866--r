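# Solvent-accessible surface area (Shrake-Rupley), buried interface area
# and per-residue relative exposure.

#' Solvent-accessible surface area per atom
#'
#' Shrake-Rupley numerical SASA: each atom's solvent-accessible sphere
#' (radius = vdW radius + probe) is sampled with a deterministic golden-
#' spiral point set, and the accessible fraction is the share of points not
#' buried inside any neighbouring atom's accessible sphere. Hydrogens are
#' excluded by default so values are comparable across heavy-atom
#' conventions (NMR models carry protons, crystal structures usually do
#' not); pass `include_hydrogens = TRUE` to keep them.
#'
#' @param struct Atom tibble.
#' @param model Model number.
#' @param chains Chains to include (default: all).
#' @param probe_radius Solvent probe radius, Angstrom (water: 1.4).
#' @param n_points Sphere sample points per atom (default 960).
#' @param include_hydrogens Keep hydrogen atoms in the calculation?
#' @param radii Named vdW radius table by element; see [vdw_radii()].
#' @param default_radius Radius used (with a warning) for unknown elements.
#' @return The selected atoms as a tibble with an added `sasa` column
#'   (Angstrom squared).
#' @export
sasa <- function(struct, model = 1, chains = NULL, probe_radius = 1.4,
                 n_points = 960, include_hydrogens = FALSE,
                 radii = vdw_radii(), default_radius = 1.70) {
  struct <- .validate_struct(struct)
  d <- struct[struct$model == model, ]
  if (!is.null(chains)) d <- d[d$chain %in% chains, ]
  if (!include_hydrogens) d <- d[d$element != "H", ]
  if (nrow(d) == 0) rlang::abort("No atoms selected.")
  r <- radii[d$element]
  if (anyNA(r)) {
    rlang::warn(sprintf("Unknown element(s) %s; using default radius %.2f A.",
                        paste(unique(d$element[is.na(r)]), collapse = ", "),
                        default_radius))
    r[is.na(r)] <- default_radius
  }
  d$sasa <- .shrake_rupley(as.matrix(d[, c("x", "y", "z")]), as.numeric(r),
                           probe_radius, n_points)
  d
}

.shrake_rupley <- function(coords, radii, probe, n_points) {
  n <- nrow(coords)
  pts <- .sphere_points(n_points)
  rr <- radii + probe
  out <- numeric(n)
  # pairwise squared distances for neighbour lists
  sq <- rowSums(coords^2)
  for (i in seq_len(n)) {
    di2 <- sq + sq[i] - 2 * as.numeric(coords %*% coords[i, ])
    nb <- which(di2 < (rr + rr[i])^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * rr[i]^2
      next
    }
    p <- pts * rr[i]
    p <- sweep(p, 2, coords[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- p[acc, 1, drop = TRUE] - coords[j, 1]
      dy <- p[acc, 2, drop = TRUE] - coords[j, 2]
      dz <- p[acc, 3, drop = TRUE] - coords[j, 3]
      acc[acc] <- (dx * dx + dy * dy + dz * dz) >= rr[j]^2
    }
    out[i] <- 4 * pi * rr[i]^2 * sum(acc) / n_points
  }
  out
}

#' Interface area buried between two chains
#'
#' Computes `(SASA(A alone) + SASA(B alone) - SASA(AB)) / 2`: the
#' per-protomer buried area, the convention used by interface servers such
#' as PISA. The unhalved total is reported alongside.
#'
#' @param struct Atom tibble.
#' @param model Model number.
#' @param chain_a,chain_b Chain identifiers.
#' @param ... Passed to [sasa()].
#' @return Tibble with columns `buried_area` (per protomer),
#'   `buried_area_total`, `sasa_a`, `sasa_b`, `sasa_complex`.
#' @export
#' @examples
#' d <- simulate_hairpin_dimer(10, 31, 85)
#' buried_interface_area(d)
buried_interface_area <- function(struct, model = 1, chain_a = "A",
                                  chain_b = "B", ...) {
  struct <- .validate_struct(struct)
  present <- unique(struct$chain[struct$model == model])
  if (!all(c(chain_a, chain_b) %in% present)) {
    rlang::abort("Both chains must be present in the model.")
  }
  sa <- sum(sasa(struct, model, chains = chain_a, ...)$sasa)
  sb <- sum(sasa(struct, model, chains = chain_b, ...)$sasa)
  sab <- sum(sasa(struct, model, chains = c(chain_a, chain_b), ...)$sasa)
  buried <- max(sa + sb - sab, 0)
  tibble::tibble(buried_area = buried / 2, buried_area_total = buried,
                 sasa_a = sa, sasa_b = sb, sasa_complex = sab)
}

#' Relative solvent exposure of a residue
#'
#' Ratio of a residue's SASA in the context of the full model to the SASA
#' of the same residue's atoms computed in isolation (extracted
#' self-reference). A fully surface-exposed residue scores near 1; a core
#' residue scores near 0.
#'
#' @param struct Atom tibble.
#' @param model Model number.
#' @param chain Chain identifier.
#' @param resno Author residue number.
#' @param ... Passed to [sasa()].
#' @return Exposure fraction.
#' @export
relative_exposure <- function(struct, model = 1, chain, resno, ...) {
  struct <- .validate_struct(struct)
  full <- sasa(struct, model, ...)
  mine <- full$chain == chain & full$resno == resno
  if (!any(mine)) rlang::abort("Residue not found.")
  in_context <- sum(full$sasa[mine])
  alone <- struct[struct$model == model & struct$chain == chain &
                    struct$resno == resno, ]
  ref <- sum(sasa(alone, model = model, ...)$sasa)
  if (ref <= 0) rlang::abort("Reference SASA is zero; cannot normalize.")
  in_context / ref
}
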