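# Independent reference implementations used as oracles. These deliberately
# re-derive each closed form from scratch rather than calling package code.

# analytic two-Gaussian mixture and its fine-grid argmax
gaussian_mix <- function(v, pos, height, sigma) {
  y <- 0
  for (i in seq_along(pos)) {
    y <- y + height[i] * exp(-0.5 * ((v - pos[i]) / sigma[i])^2)
  }
  y
}

gaussian_mix_argmax <- function(pos, height, sigma, lo, hi) {
  v <- seq(lo, hi, length.out = 2e5)
  v[which.max(gaussian_mix(v, pos, height, sigma))]
}

# reference 15N rates from scratch (rigid isotropic rotor)
ref_n15_rigid <- function(tau_c_ns, field_mhz) {
  gh <- 2.6752218744e8; gn <- -2.71261804e7
  mu0 <- 4e-7 * pi; hbar <- 1.054571817e-34
  rnh <- 1.02e-10; csa <- -160e-6
  tc <- tau_c_ns * 1e-9
  wh <- 2 * pi * field_mhz * 1e6
  wn <- wh * gn / gh
  d2 <- (mu0 / (4 * pi) * hbar * gh * gn / rnh^3)^2 / 4
  c2 <- (wn * csa)^2 / 3
  J <- function(w) 0.4 * tc / (1 + (w * tc)^2)
  r1 <- d2 * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) + c2 * J(wn)
  r2 <- 0.5 * d2 * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) +
                      6 * J(wh + wn)) + (c2 / 6) * (4 * J(0) + 3 * J(wn))
  noe <- 1 + d2 * (gh / gn) * (6 * J(wh + wn) - J(wh - wn)) / r1
  list(r1 = r1, r2 = r2, noe = noe)
}

# bisection solve of the N2 <-> 2U mass-action equation for fU
ref_unfolded_fraction <- function(temp_k, dh_kj, tm_k, ct) {
  R <- 8.31446261815324
  K <- ct * exp(-(dh_kj * 1000 / R) * (1 / temp_k - 1 / tm_k))
  f <- function(fu) 2 * ct * fu^2 / (1 - fu) - K
  lo <- 1e-12; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# exact exposed area of sphere 1 (radius R1 + probe) against sphere 2,
# by the spherical-cap construction
ref_two_sphere_area <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d <= abs(R1 - R2)) {
    return(if (R1 > R2) 4 * pi * R1^2 else 0)
  }
  # height of the buried cap on sphere 1
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# dense-grid numerical exposure of sphere 1 against sphere 2 (latitude
# bands, independent of the package's golden-spiral sampling)
ref_two_sphere_area_grid <- function(r1, r2, d, probe = 1.4, n_lat = 400) {
  R1 <- r1 + probe; R2 <- r2 + probe
  theta <- (seq_len(n_lat) - 0.5) / n_lat * pi
  acc <- 0
  for (th in theta) {
    n_lon <- max(8, round(2 * n_lat * sin(th)))
    phi <- (seq_len(n_lon) - 0.5) / n_lon * 2 * pi
    p <- cbind(R1 * sin(th) * cos(phi), R1 * sin(th) * sin(phi),
               rep(R1 * cos(th), n_lon))
    w <- sin(th) * (pi / n_lat) * (2 * pi / n_lon) * R1^2
    dist2 <- (p[, 1] - d)^2 + p[, 2]^2 + p[, 3]^2
    acc <- acc + w * sum(dist2 >= R2^2)
  }
  acc
}

# brute-force all-pairs inter-chain heavy-atom contact scan (residue pairs
# with any carbon-carbon distance <= cutoff between apolar side chains)
ref_nonpolar_pairs <- function(struct, model = 1, cutoff = 4.5) {
  apolar <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")
  d <- struct[struct$model == model & struct$element == "C" &
                struct$resname %in% apolar &
                !(struct$atom %in% c("N", "CA", "C", "O")), ]
  out <- character()
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(d))) {
      if (j <= i) next
      a <- d[i, ]; b <- d[j, ]
      if (a$chain == b$chain && abs(a$resno - b$resno) < 2) next
      dist <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
      if (dist <= cutoff) {
        key <- paste(sort(c(paste(a$chain, a$resno), paste(b$chain, b$resno))),
                     collapse = "|")
        out <- c(out, key)
      }
    }
  }
  sort(unique(out))
}

# minimal two-chain toy structure builder
toy_struct <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(model = 1L, chain = r$chain, resno = r$resno,
                   resname = r$resname, atom = r$atom,
                   element = r$element %||% substr(gsub("[0-9]", "", r$atom), 1, 1),
                   x = r$xyz[1], y = r$xyz[2], z = r$xyz[3])
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
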