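# Ideal helical-hairpin dimer generator. Backbone-only poly-alanine helices
# are built from internal coordinates, aligned along analytic directions,
# and assembled into a two-chain dimer with a controlled inter-helix
# crossing angle, protomer docking angle and inter-protomer gap — a ground
# truth for every geometry estimator in the package.

# place atom D given positions a, b, c, a bond length c-D, the angle
# b-c-D (degrees) and the dihedral a-b-c-D (degrees): standard internal-
# to-Cartesian (NeRF) construction
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180 # frame handedness: negate so that the
                              # measured a-b-c-D torsion equals `dihedral`
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(M %*% d2 + c)
}

# ideal backbone bond lengths / angles (poly-Ala averages)
.bb <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

# build an n-residue ideal helix (N, CA, C, O), phi/psi fixed;
# returns list(atoms = tibble(resno, atom, x, y, z))
.build_helix <- function(n_res, phi = -60, psi = -45, omega = 180) {
  b <- .bb
  # seed the first three mainchain atoms
  pos <- list(
    N1 = c(0, 0, 0),
    CA1 = c(b$n_ca, 0, 0)
  )
  pos$C1 <- .place_atom(c(-1, 1, 0), pos$N1, pos$CA1, b$ca_c, b$ang_n_ca_c, psi - 120)
  atoms <- list(
    list(1L, "N", pos$N1), list(1L, "CA", pos$CA1), list(1L, "C", pos$C1))
  prev <- list(N = pos$N1, CA = pos$CA1, C = pos$C1)
  for (i in seq_len(n_res - 1)) {
    Np <- .place_atom(prev$N, prev$CA, prev$C, b$c_n, b$ang_ca_c_n, psi)
    CAp <- .place_atom(prev$CA, prev$C, Np, b$n_ca, b$ang_c_n_ca, omega)
    Cp <- .place_atom(prev$C, Np, CAp, b$ca_c, b$ang_n_ca_c, phi)
    # carbonyl O of the previous residue, anti to the next N
    Op <- .place_atom(prev$N, prev$CA, prev$C, b$c_o, b$ang_ca_c_o, psi + 180)
    atoms[[length(atoms) + 1L]] <- list(i, "O", Op)
    atoms[[length(atoms) + 1L]] <- list(i + 1L, "N", Np)
    atoms[[length(atoms) + 1L]] <- list(i + 1L, "CA", CAp)
    atoms[[length(atoms) + 1L]] <- list(i + 1L, "C", Cp)
    prev <- list(N = Np, CA = CAp, C = Cp)
  }
  # last carbonyl O (psi undefined; continue the helical twist)
  Ol <- .place_atom(prev$N, prev$CA, prev$C, b$c_o, b$ang_ca_c_o, psi + 180)
  atoms[[length(atoms) + 1L]] <- list(n_res, "O", Ol)
  m <- do.call(rbind, lapply(atoms, function(a) {
    data.frame(resno = a[[1]], atom = a[[2]], x = a[[3]][1], y = a[[3]][2],
               z = a[[3]][3])
  }))
  m[order(m$resno, match(m$atom, c("N", "CA", "C", "O"))), ]
}

# rigid transform of the x,y,z columns
.transform_atoms <- function(df, R = diag(3), t = c(0, 0, 0)) {
  co <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- co[, 1] + t[1]; df$y <- co[, 2] + t[2]; df$z <- co[, 3] + t[3]
  df
}

# center a helix on the origin with its fitted CA axis along `direction`
.orient_helix <- function(helix, direction) {
  ca <- as.matrix(helix[helix$atom == "CA", c("x", "y", "z")])
  ax <- fit_helix_axis(ca)
  helix <- .transform_atoms(helix, t = -ax$centroid)
  .transform_atoms(helix, R = .rotation_between(ax$axis, direction))
}

.min_interchain_dist <- function(a, b) {
  ca <- as.matrix(a[, c("x", "y", "z")])
  cb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ca^2), rep(1, nrow(cb))) +
    outer(rep(1, nrow(ca)), rowSums(cb^2)) - 2 * ca %*% t(cb)
  sqrt(max(min(d2), 0))
}

#' Simulate an ideal alpha-helical hairpin dimer
#'
#' Builds a backbone-only (N, CA, C, O) two-chain dimer in which each
#' protomer is an antiparallel pair of ideal helices whose axes cross at
#' `interhelix_angle_deg`, and the two protomers' hairpin principal axes
#' cross at `docking_angle_deg`. Chain B is a rigid copy of chain A rotated
#' about an axis perpendicular to A's principal axis and then translated
#' until the closest inter-chain atom pair sits at `inter_protomer_gap`
#' Angstrom, so the requested angles are recovered exactly by the package's
#' own axis estimators and no atoms clash.
#'
#' @param residues_per_helix Residues in each helix (>= 6).
#' @param interhelix_angle_deg Crossing angle of the two helices within a
#'   protomer, degrees in `[0, 90]`.
#' @param docking_angle_deg Crossing angle of the two protomer principal
#'   axes, degrees in `[0, 90]`.
#' @param helix_separation Distance between the two helix axes of a
#'   protomer, Angstrom.
#' @param inter_protomer_gap Closest allowed inter-chain atom distance,
#'   Angstrom.
#' @param protomer_offset Optional explicit chain-B translation distance
#'   (Angstrom) along the packing direction; if the resulting closest
#'   approach is below `inter_protomer_gap` the geometry is rejected.
#' @param phi,psi Backbone dihedrals of the ideal helix, degrees.
#' @return Atom tibble (single model) with chains `"A"` and `"B"`; the
#'   requested geometry is stored in attribute `"truth"`.
#' @export
#' @examples
#' dim1 <- simulate_hairpin_dimer(14, 31, 85)
#' docking_angle(dim1)
simulate_hairpin_dimer <- function(residues_per_helix = 14,
                                   interhelix_angle_deg = 31,
                                   docking_angle_deg = 85,
                                   helix_separation = 9.5,
                                   inter_protomer_gap = 4,
                                   protomer_offset = NULL,
                                   phi = -60, psi = -45) {
  if (residues_per_helix < 6) rlang::abort("Need >= 6 residues per helix.")
  if (interhelix_angle_deg < 0 || interhelix_angle_deg > 90 ||
      docking_angle_deg < 0 || docking_angle_deg > 90) {
    rlang::abort("Angles must lie in [0, 90] degrees.")
  }
  if (inter_protomer_gap <= 0) rlang::abort("`inter_protomer_gap` must be > 0.")

  helix <- .build_helix(residues_per_helix, phi = phi, psi = psi)
  th <- interhelix_angle_deg * pi / 180
  d1 <- c(sin(th / 2), 0, cos(th / 2))
  d2 <- c(sin(th / 2), 0, -cos(th / 2)) # antiparallel partner
  h1 <- .transform_atoms(.orient_helix(helix, d1),
                         t = c(0, -helix_separation / 2, 0))
  h2 <- .orient_helix(helix, d2)
  h2 <- .transform_atoms(h2, t = c(0, helix_separation / 2, 0))
  h2$resno <- h2$resno + residues_per_helix + 2L
  chainA <- rbind(h1, h2)

  # chain B: rigid copy rotated about an axis perpendicular to A's
  # measured hairpin axis (the bundle direction of its two helix axes,
  # matching the docking_angle() estimator), then packed along the mutual
  # perpendicular
  ax1 <- fit_helix_axis(as.matrix(h1[h1$atom == "CA", c("x", "y", "z")]))$axis
  ax2 <- fit_helix_axis(as.matrix(h2[h2$atom == "CA", c("x", "y", "z")]))$axis
  a_axis <- eigen(ax1 %o% ax1 + ax2 %o% ax2, symmetric = TRUE)$vectors[, 1]
  r_axis <- .unit(.cross3(a_axis, c(1, 0, 0)))
  if (sqrt(sum(.cross3(a_axis, c(1, 0, 0))^2)) < 1e-6) {
    r_axis <- .unit(.cross3(a_axis, c(0, 1, 0)))
  }
  R <- .rotation_about(r_axis, docking_angle_deg * pi / 180)
  chainB <- .transform_atoms(chainA, R = R)
  t_dir <- .unit(.cross3(a_axis, r_axis))

  shift_b <- function(dist) .transform_atoms(chainB, t = t_dir * dist)
  if (!is.null(protomer_offset)) {
    chainB <- shift_b(protomer_offset)
    gap <- .min_interchain_dist(chainA, chainB)
    if (gap < inter_protomer_gap) {
      rlang::abort(sprintf(
        "Impossible geometry: offset %.1f A leaves a %.2f A contact (< gap %.2f A).",
        protomer_offset, gap, inter_protomer_gap))
    }
  } else {
    lo <- 0; hi <- 10
    while (.min_interchain_dist(chainA, shift_b(hi)) < inter_protomer_gap) {
      hi <- hi + 10
      if (hi > 500) rlang::abort("Cannot separate protomers; geometry degenerate.")
    }
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (.min_interchain_dist(chainA, shift_b(mid)) < inter_protomer_gap) {
        lo <- mid
      } else {
        hi <- mid
      }
    }
    chainB <- shift_b(hi)
  }

  mk <- function(df, ch) {
    tibble::tibble(
      model = 1L, chain = ch, resno = as.integer(df$resno), resname = "ALA",
      atom = df$atom, element = substr(df$atom, 1, 1),
      x = df$x, y = df$y, z = df$z
    )
  }
  out <- dplyr::bind_rows(mk(chainA, "A"), mk(chainB, "B"))
  attr(out, "truth") <- list(
    residues_per_helix = residues_per_helix,
    interhelix_angle_deg = interhelix_angle_deg,
    docking_angle_deg = docking_angle_deg,
    helix_separation = helix_separation,
    inter_protomer_gap = inter_protomer_gap
  )
  out
}

#' Jittered copies of a single model as a synthetic ensemble
#'
#' Stacks `n_models` copies of model 1 of `struct`, adding iid Gaussian
#' noise to every coordinate — a minimal emulation of the coordinate spread
#' of an NMR ensemble, with known per-atom displacement statistics.
#'
#' @param struct Atom tibble (model 1 is used).
#' @param n_models Number of models in the output ensemble.
#' @param coord_sd Per-coordinate jitter standard deviation, Angstrom.
#' @param seed Integer seed.
#' @return Atom tibble with models `1..n_models`.
#' @export
simulate_ensemble <- function(struct, n_models = 20, coord_sd = 0.5,
                              seed = NULL) {
  struct <- .validate_struct(struct)
  base <- struct[struct$model == min(struct$model), ]
  .with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_models), function(m) {
      d <- base
      d$model <- m
      if (coord_sd > 0) {
        d$x <- d$x + rnorm(nrow(d), 0, coord_sd)
        d$y <- d$y + rnorm(nrow(d), 0, coord_sd)
        d$z <- d$z + rnorm(nrow(d), 0, coord_sd)
      }
      d
    }))
  })
}
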