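# Helix detection, axis fitting, crossing/docking angles, superposition and
# ensemble precision for multi-model coordinate ensembles.

#' Fit a helix axis by principal components
#'
#' The axis is the principal direction (largest singular value) of the
#' centered C-alpha cloud, oriented from the N- towards the C-terminus; the
#' residual spread perpendicular to the axis approximates the helix radius.
#'
#' @param ca_coords Numeric matrix (n x 3) of C-alpha coordinates in chain
#'   order, n >= 6.
#' @return List with `axis` (unit vector), `centroid`, and `fit_rms`
#'   (root-mean-square distance of the points from the axis line, Angstrom).
#' @export
fit_helix_axis <- function(ca_coords) {
  ca_coords <- as.matrix(ca_coords)
  if (nrow(ca_coords) < 6) rlang::abort("Need >= 6 C-alpha positions.")
  centroid <- colMeans(ca_coords)
  centered <- sweep(ca_coords, 2, centroid)
  sv <- svd(centered)
  axis <- sv$v[, 1]
  # orient N -> C
  if (sum((ca_coords[nrow(ca_coords), ] - ca_coords[1, ]) * axis) < 0) {
    axis <- -axis
  }
  proj <- centered %*% axis
  perp <- centered - proj %*% t(axis)
  list(axis = as.numeric(axis), centroid = as.numeric(centroid),
       fit_rms = sqrt(mean(rowSums(perp^2))))
}

#' Sign-independent crossing angle between two axes
#'
#' Returns `min(theta, 180 - theta)` in degrees, i.e. the crossing angle of
#' two lines irrespective of the direction chosen along each axis.
#'
#' @param axis_a,axis_b Numeric length-3 vectors (need not be normalized,
#'   but must be non-zero).
#' @return Angle in degrees, in `[0, 90]`.
#' @export
#' @examples
#' crossing_angle(c(0, 0, 1), c(1, 0, 1)) # 45
crossing_angle <- function(axis_a, axis_b) {
  a <- .unit(as.numeric(axis_a)); b <- .unit(as.numeric(axis_b))
  acos(pmin(abs(sum(a * b)), 1)) * 180 / pi
}

# per-residue backbone dihedrals for one chain of one model
.phi_psi <- function(struct, model = 1, chain = NULL) {
  d <- struct[struct$model == model, ]
  if (!is.null(chain)) d <- d[d$chain == chain, ]
  d <- d[d$atom %in% c("N", "CA", "C"), ]
  resnos <- sort(unique(d$resno))
  get <- function(rn, at) {
    r <- d[d$resno == rn & d$atom == at, ]
    if (nrow(r) != 1) return(NULL)
    c(r$x, r$y, r$z)
  }
  out <- lapply(resnos, function(rn) {
    Np <- get(rn, "N"); CAp <- get(rn, "CA"); Cp <- get(rn, "C")
    if (is.null(Np) || is.null(CAp) || is.null(Cp)) {
      rlang::warn(sprintf("Residue %d lacks backbone atoms; skipped.", rn))
      return(tibble::tibble(resno = rn, phi = NA_real_, psi = NA_real_))
    }
    Cprev <- get(rn - 1, "C")
    Nnext <- get(rn + 1, "N")
    phi <- if (is.null(Cprev)) NA_real_ else .dihedral(Cprev, Np, CAp, Cp)
    psi <- if (is.null(Nnext)) NA_real_ else .dihedral(Np, CAp, Cp, Nnext)
    tibble::tibble(resno = rn, phi = phi, psi = psi)
  })
  dplyr::bind_rows(out)
}

#' Assign helical segments from backbone dihedrals
#'
#' Residues whose backbone dihedrals fall inside the alpha-helical window
#' (`phi_range`, `psi_range`) in runs of at least `min_len` residues are
#' assigned to helices; single-residue gaps inside a run are bridged.
#' Terminal residues with an undefined phi or psi are accepted when the
#' defined dihedral is helical. For each segment of six or more residues the
#' C-alpha axis is fitted with [fit_helix_axis()].
#'
#' @param struct Atom tibble.
#' @param model Model number (default 1).
#' @param chain Chain identifier, or `NULL` for all chains.
#' @param phi_range,psi_range Helical windows, degrees.
#' @param min_len Minimum run length.
#' @return Tibble with columns `chain`, `first_residue`, `last_residue`,
#'   `n_residues`, plus list-columns `axis`, `centroid` and numeric
#'   `fit_rms` (NA for segments shorter than 6 residues).
#' @export
assign_helices <- function(struct, model = 1, chain = NULL,
                           phi_range = c(-100, -30), psi_range = c(-67, -7),
                           min_len = 4) {
  struct <- .validate_struct(struct)
  chains <- if (is.null(chain)) {
    sort(unique(struct$chain[struct$model == model]))
  } else chain
  out <- lapply(chains, function(ch) {
    tor <- .phi_psi(struct, model, ch)
    if (nrow(tor) == 0) return(NULL)
    ok_phi <- !is.na(tor$phi) &
      tor$phi >= phi_range[1] & tor$phi <= phi_range[2]
    ok_psi <- !is.na(tor$psi) &
      tor$psi >= psi_range[1] & tor$psi <= psi_range[2]
    helical <- (ok_phi & ok_psi) |
      (is.na(tor$phi) & ok_psi) | (is.na(tor$psi) & ok_phi)
    # never merge across breaks in the residue numbering
    grp <- cumsum(c(0L, as.integer(diff(tor$resno) != 1L)))
    runs <- dplyr::bind_rows(lapply(split(seq_along(helical), grp), function(ix) {
      r <- .runs_with_gaps(helical[ix], min_len)
      r$start <- ix[r$start]; r$end <- ix[r$end]
      r
    }))
    if (nrow(runs) == 0) return(NULL)
    seg <- lapply(seq_len(nrow(runs)), function(i) {
      rn <- tor$resno[runs$start[i]:runs$end[i]]
      ca <- .model_coords(struct, model, ch, atoms = "CA", resno = rn)
      ax <- if (nrow(ca) >= 6) fit_helix_axis(ca) else
        list(axis = NULL, centroid = NULL, fit_rms = NA_real_)
      tibble::tibble(
        chain = ch,
        first_residue = rn[1], last_residue = rn[length(rn)],
        n_residues = length(rn),
        axis = list(ax$axis), centroid = list(ax$centroid),
        fit_rms = ax$fit_rms
      )
    })
    dplyr::bind_rows(seg)
  })
  dplyr::bind_rows(out)
}

# hairpin axis of one chain: the principal direction of the bundle of
# fitted helix axes (length-weighted sum of axis outer products). For an
# antiparallel hairpin this is the orientation-free mean helix direction;
# unlike the raw principal component of the C-alpha cloud it does not
# become degenerate with the inter-helix separation direction.
.protomer_axis <- function(struct, model, chain, ...) {
  segs <- assign_helices(struct, model, chain, ...)
  segs <- segs[!is.na(segs$fit_rms), ]
  if (is.null(segs) || nrow(segs) == 0) {
    rlang::abort(sprintf("Chain %s has no helical segments of >= 6 residues.",
                         chain))
  }
  M <- matrix(0, 3, 3)
  for (i in seq_len(nrow(segs))) {
    a <- segs$axis[[i]]
    M <- M + segs$n_residues[i] * (a %o% a)
  }
  eigen(M, symmetric = TRUE)$vectors[, 1]
}

#' Docking angle between two protomers
#'
#' The crossing angle between the two chains' hairpin axes. Each chain's
#' hairpin axis is the principal direction of its bundle of fitted helix
#' axes (length-weighted, orientation-free), i.e. the mean helix direction
#' of the antiparallel pair — a definition that stays well-conditioned
#' where the raw principal component of the C-alpha cloud would be nearly
#' degenerate with the inter-helix offset direction.
#'
#' @param struct Atom tibble with at least two chains.
#' @param model Model number.
#' @param chains Length-2 character vector; defaults to the first two
#'   chains present.
#' @param ... Passed to [assign_helices()].
#' @return Angle in degrees, in `[0, 90]`.
#' @export
docking_angle <- function(struct, model = 1, chains = NULL, ...) {
  struct <- .validate_struct(struct)
  present <- sort(unique(struct$chain[struct$model == model]))
  if (length(present) < 2) rlang::abort("Need two chains for a docking angle.")
  if (is.null(chains)) {
    chains <- present[1:2]
    if (length(present) > 2) {
      rlang::warn(sprintf("Multiple chains; using %s and %s.",
                          chains[1], chains[2]))
    }
  }
  a <- .protomer_axis(struct, model, chains[1], ...)
  b <- .protomer_axis(struct, model, chains[2], ...)
  crossing_angle(a, b)
}

#' Least-squares rigid-body superposition
#'
#' Optimal rotation/translation of `mobile` onto `reference` by the standard
#' SVD construction (Kabsch), with a proper rotation enforced.
#'
#' @param mobile,reference Paired coordinate matrices (n x 3, n >= 3,
#'   non-collinear).
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   after transformation, and `coords`, the transformed mobile coordinates
#'   (`coords = mobile %*% t(rotation) + translation`).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    rlang::abort("`mobile` and `reference` must be equal-sized n x 3 matrices.")
  }
  if (nrow(mobile) < 3) rlang::abort("Need >= 3 paired points.")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (max(svd(A)$d) < 1e-10) rlang::abort("Degenerate (collapsed) point set.")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  coords <- A %*% t(R)
  coords <- sweep(coords, 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((coords - reference)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)),
       rmsd = rmsd, coords = coords)
}

#' Coordinate precision of a structure ensemble
#'
#' Iteratively superposes every model onto the evolving mean structure until
#' the mean stabilizes (change < `tol` Angstrom), then reports the mean and
#' standard deviation of the per-model RMSD to the mean — the conventional
#' precision statistic quoted for NMR ensembles.
#'
#' @param struct Atom tibble with >= 2 models.
#' @param chains Chains to include (default: all).
#' @param residues Residue numbers to include (default: all).
#' @param mode `"backbone"` (N, CA, C, O) or `"heavy"` (all non-hydrogen).
#' @param tol Convergence tolerance on the mean coordinates, Angstrom.
#' @return Tibble with columns `mean_rmsd`, `sd_rmsd`, `n_models`, `n_atoms`.
#' @export
ensemble_rmsd <- function(struct, chains = NULL, residues = NULL,
                          mode = c("backbone", "heavy"), tol = 1e-4) {
  mode <- match.arg(mode)
  struct <- .validate_struct(struct)
  models <- sort(unique(struct$model))
  if (length(models) < 2) rlang::abort("Need an ensemble of >= 2 models.")
  sel <- struct
  if (!is.null(chains)) sel <- sel[sel$chain %in% chains, ]
  if (!is.null(residues)) sel <- sel[sel$resno %in% residues, ]
  sel <- if (mode == "backbone") {
    sel[sel$atom %in% .backbone_atoms, ]
  } else {
    sel[sel$element != "H", ]
  }
  if (nrow(sel) == 0) rlang::abort("Empty atom selection.")
  coords <- lapply(models, function(m) {
    as.matrix(sel[sel$model == m, c("x", "y", "z")])
  })
  n <- vapply(coords, nrow, integer(1))
  if (length(unique(n)) != 1) rlang::abort("Selection differs between models.")

  mean_c <- coords[[1]]
  for (iter in 1:100) {
    fitted <- lapply(coords, function(co) superpose(co, mean_c)$coords)
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    delta <- sqrt(mean(rowSums((new_mean - mean_c)^2)))
    mean_c <- new_mean
    if (delta < tol) break
  }
  rmsds <- vapply(coords, function(co) superpose(co, mean_c)$rmsd, numeric(1))
  tibble::tibble(mean_rmsd = mean(rmsds), sd_rmsd = sd(rmsds),
                 n_models = length(models), n_atoms = n[1])
}
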