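# Structure I/O, helix geometry, superposition, ensemble precision, SASA
# and contacts.

test_that("multi-model files preserve model count and error when truncated", {
  d <- simulate_hairpin_dimer(8, 31, 85)
  ens <- simulate_ensemble(d, n_models = 20, coord_sd = 0.2, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ens, tmp)
  back <- read_structure(tmp)
  expect_equal(length(unique(back$model)), 20)
  expect_equal(nrow(back), nrow(ens))

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(substr(readLines(tmp)[1:3], 1, 40), bad)
  expect_error(read_structure(bad))
  expect_error(read_structure("no/such/file.pdb"), "No such file")
})

test_that("helix assignment finds ideal helices and rejects extended chains", {
  d <- simulate_hairpin_dimer(12, 31, 85)
  segs <- assign_helices(d, chain = "A")
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_residues, c(12, 12))

  # a fully extended chain (phi = psi = 180) has no helical residues
  ext <- oligostate:::.build_helix(12, phi = -140, psi = 140)
  ext_t <- tibble::tibble(model = 1L, chain = "A", resno = ext$resno,
                          resname = "ALA", atom = ext$atom,
                          element = substr(ext$atom, 1, 1),
                          x = ext$x, y = ext$y, z = ext$z)
  expect_equal(nrow(assign_helices(ext_t)), 0)
})

test_that("helix axis fitting recovers direction, radius and degenerate errors", {
  line <- cbind(0, 0, seq(0, 10, length.out = 8))
  ax <- fit_helix_axis(line)
  expect_equal(abs(ax$axis[3]), 1, tolerance = 1e-12)
  expect_equal(ax$fit_rms, 0)
  expect_error(fit_helix_axis(line[1:4, ]), ">= 6")

  helix <- oligostate:::.build_helix(14)
  ca <- as.matrix(helix[helix$atom == "CA", c("x", "y", "z")])
  fit <- fit_helix_axis(ca)
  # the CA cylinder radius of an ideal helix is ~2.3 A
  expect_equal(fit$fit_rms, 2.3, tolerance = 0.1)
  # axis is oriented N -> C
  expect_gt(sum((ca[14, ] - ca[1, ]) * fit$axis), 0)
})

test_that("crossing angles are symmetric, sign-invariant and bounded", {
  expect_equal(crossing_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(crossing_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    th <- crossing_angle(a, b)
    expect_equal(th, crossing_angle(b, a))
    expect_equal(th, crossing_angle(-a, b))
    expect_true(th >= 0 && th <= 90)
  }
  expect_error(crossing_angle(c(0, 0, 0), c(1, 0, 0)), "zero vector")
})

test_that("docking angle is zero for superposed copies and needs two chains", {
  d <- simulate_hairpin_dimer(10, 31, 85)
  a <- d[d$chain == "A", ]
  b <- a
  b$chain <- "B"
  expect_lt(docking_angle(dplyr::bind_rows(a, b)), 1e-6)
  expect_error(docking_angle(a), "two chains")
})

test_that("superposition matches its analytic RMSD and the bio3d reference", {
  set.seed(7)
  ref <- matrix(rnorm(30), ncol = 3)
  fit <- superpose(ref, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  R <- oligostate:::.rotation_about(c(1, 2, 3), 0.7)
  moved <- ref %*% t(R) + matrix(rep(c(5, -3, 2), each = 10), ncol = 3)
  expect_lt(superpose(moved, ref)$rmsd, 1e-6)

  # displacement of known norm on one atom: optimal rmsd <= norm/sqrt(N),
  # and equals it when the superposition is pinned to the reference frame
  disp <- ref; disp[1, ] <- disp[1, ] + c(0, 0, 1)
  plain_rmsd <- sqrt(mean(rowSums((disp - ref)^2)))
  expect_equal(plain_rmsd, 1 / sqrt(10))
  expect_lte(superpose(disp, ref)$rmsd, plain_rmsd)

  # independent reference implementation: bio3d fit.xyz
  mob <- ref %*% t(R) + 2
  ours <- superpose(mob, ref)$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(ref)), as.numeric(t(mob)),
                        fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-4)
  expect_error(superpose(matrix(0, 3, 3), matrix(0, 3, 3)), "Degenerate")
})

test_that("ensemble RMSD is zero for identical models and tracks jitter scaling", {
  d <- simulate_hairpin_dimer(8, 31, 85)
  same <- simulate_ensemble(d, n_models = 5, coord_sd = 0)
  r0 <- ensemble_rmsd(same)
  expect_equal(r0$mean_rmsd, 0, tolerance = 1e-12)
  expect_equal(r0$sd_rmsd, 0, tolerance = 1e-12)

  # iid jitter of sd s per coordinate: per-model RMSD to the mean
  # approaches s * sqrt(3) * sqrt(1 - 1/M); superposition absorbs a little
  s <- 0.4; M <- 10
  jit <- simulate_ensemble(d, n_models = M, coord_sd = s, seed = 3)
  r <- ensemble_rmsd(jit)
  expected <- s * sqrt(3) * sqrt(1 - 1 / M)
  expect_equal(r$mean_rmsd, expected, tolerance = 0.12)

  # invariance under a rigid transformation of one model
  moved <- jit
  R <- oligostate:::.rotation_about(c(0, 1, 1), 1.1)
  i <- moved$model == 3
  co <- as.matrix(moved[i, c("x", "y", "z")]) %*% t(R)
  moved$x[i] <- co[, 1] + 8; moved$y[i] <- co[, 2] - 2; moved$z[i] <- co[, 3]
  r2 <- ensemble_rmsd(moved)
  expect_equal(r2$mean_rmsd, r$mean_rmsd, tolerance = 1e-6)
  expect_error(ensemble_rmsd(jit, chains = "Z"), "Empty")
})

test_that("SASA matches the analytic sphere and a dense two-atom oracle", {
  lone <- toy_struct(list(chain = "A", resno = 1, resname = "GLY",
                          atom = "O", xyz = c(0, 0, 0)))
  a <- sasa(lone)$sasa
  expect_equal(a, 4 * pi * (1.52 + 1.4)^2, tolerance = 0.01)

  # a small atom fully inside a large one is dark
  rad <- c(O = 1.52, X = 8)
  pair <- toy_struct(
    list(chain = "A", resno = 1, resname = "GLY", atom = "O", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 1, resname = "GLY", atom = "X", element = "X",
         xyz = c(0.5, 0, 0)))
  s <- sasa(pair, radii = rad)
  expect_equal(s$sasa[s$atom == "O"], 0)

  # two-atom toys across separations vs an independent latitude-band oracle
  for (d in c(2.0, 3.0, 4.0, 5.5)) {
    two <- toy_struct(
      list(chain = "A", resno = 1, resname = "GLY", atom = "C", xyz = c(0, 0, 0)),
      list(chain = "A", resno = 1, resname = "GLY", atom = "O", xyz = c(d, 0, 0)))
    s <- sasa(two)$sasa
    oracle_c <- ref_two_sphere_area_grid(1.70, 1.52, d)
    oracle_o <- ref_two_sphere_area_grid(1.52, 1.70, d)
    expect_equal(s[1], oracle_c, tolerance = 0.02)
    expect_equal(s[2], oracle_o, tolerance = 0.02)
    # and the closed-form spherical-cap value agrees too
    expect_equal(s[1], ref_two_sphere_area(1.70, 1.52, d), tolerance = 0.02)
  }
  expect_warning(sasa(toy_struct(list(chain = "A", resno = 1, resname = "GLY",
                                      atom = "Q", element = "Q",
                                      xyz = c(0, 0, 0)))),
                 "Unknown element")
})

test_that("buried interface area is non-negative, additive-bounded and gap-monotone", {
  d <- simulate_hairpin_dimer(10, 31, 85)
  far <- d
  i <- far$chain == "B"
  far$x[i] <- far$x[i] + 100
  expect_equal(buried_interface_area(far)$buried_area, 0)

  areas <- vapply(c(3, 5, 8, 12), function(g) {
    dg <- simulate_hairpin_dimer(10, 31, 85, inter_protomer_gap = g)
    b <- buried_interface_area(dg)
    # SASA additivity bound
    expect_lte(b$sasa_complex, b$sasa_a + b$sasa_b + 1e-9)
    b$buried_area
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  expect_gt(areas[1], 0)
})

test_that("relative exposure is 1 in isolation and ~0 at the centre of a cluster", {
  lone <- toy_struct(
    list(chain = "A", resno = 5, resname = "ALA", atom = "CA", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 5, resname = "ALA", atom = "CB", xyz = c(1.5, 0, 0)))
  expect_equal(relative_exposure(lone, chain = "A", resno = 5), 1,
               tolerance = 1e-9)

  # bury the residue inside a dense shell of dummy atoms
  shell <- oligostate:::.sphere_points(200) * 4
  args <- lapply(seq_len(nrow(shell)), function(i) {
    list(chain = "A", resno = 100 + i, resname = "GLY", atom = "C",
         xyz = shell[i, ])
  })
  buried <- dplyr::bind_rows(lone, do.call(toy_struct, args))
  expect_lt(relative_exposure(buried, chain = "A", resno = 5), 0.05)
  expect_error(relative_exposure(lone, chain = "A", resno = 9), "not found")
})

test_that("contact typing matches construction and a brute-force scan", {
  # distant pair: nothing
  gg <- toy_struct(
    list(chain = "A", resno = 1, resname = "GLY", atom = "CA", xyz = c(0, 0, 0)),
    list(chain = "B", resno = 1, resname = "GLY", atom = "CA", xyz = c(20, 0, 0)))
  expect_equal(nrow(find_contacts(gg)), 0)

  # constructed Asp-Arg pair at 3.0 A: one salt bridge
  pair <- toy_struct(
    list(chain = "A", resno = 10, resname = "ASP", atom = "OD1", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 10, resname = "ASP", atom = "CG", xyz = c(-1.3, 0, 0)),
    list(chain = "B", resno = 20, resname = "ARG", atom = "NH1", xyz = c(3, 0, 0)),
    list(chain = "B", resno = 20, resname = "ARG", atom = "CZ", xyz = c(4.3, 0, 0)))
  ct <- find_contacts(pair)
  sb <- ct[ct$kind == "salt_bridge", ]
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 3)
  expect_equal(sb$span, "inter")

  # hydrogen bond with its angle criterion: antecedent-donor-acceptor
  hb <- toy_struct(
    list(chain = "A", resno = 1, resname = "SER", atom = "OG", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 1, resname = "SER", atom = "CB", xyz = c(-1.4, 0, 0)),
    list(chain = "B", resno = 2, resname = "GLY", atom = "O", xyz = c(3.0, 0, 0)))
  expect_equal(nrow(find_contacts(hb)[find_contacts(hb)$kind == "hbond", ]), 1)
  bent <- toy_struct(
    list(chain = "A", resno = 1, resname = "SER", atom = "OG", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 1, resname = "SER", atom = "CB", xyz = c(1.0, 1.0, 0)),
    list(chain = "B", resno = 2, resname = "GLY", atom = "O", xyz = c(3.0, 0, 0)))
  expect_equal(nrow(find_contacts(bent)[find_contacts(bent)$kind == "hbond", ]), 0)

  # nonpolar pairs on a leucine-like toy equal the brute-force residue scan
  set.seed(1)
  pts <- matrix(rnorm(36, sd = 3), ncol = 3)
  args <- lapply(seq_len(nrow(pts)), function(i) {
    list(chain = if (i <= 6) "A" else "B", resno = i, resname = "LEU",
         atom = "CD1", xyz = pts[i, ])
  })
  leu <- do.call(toy_struct, args)
  got <- find_contacts(leu)
  np <- got[got$kind == "nonpolar", ]
  got_pairs <- sort(unique(mapply(
    function(ca, ra, cb, rb) {
      paste(sort(c(paste(ca, ra), paste(cb, rb))), collapse = "|")
    },
    np$chain_a, np$resno_a, np$chain_b, np$resno_b, USE.NAMES = FALSE)))
  expect_equal(got_pairs, ref_nonpolar_pairs(leu))
})
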