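# Synthetic-data generators: determinism, exact closed forms, ground-truth
# recovery hooks.

test_that("generators are bit-reproducible given a seed", {
  p <- tibble::tibble(position_ml = 1.4, height = 1, sigma_ml = 0.03)
  expect_identical(simulate_chromatogram(p, noise_sd = 0.01, seed = 11),
                   simulate_chromatogram(p, noise_sd = 0.01, seed = 11))
  expect_identical(
    simulate_relaxation(30, noise_fraction = 0.03, seed = 5),
    simulate_relaxation(30, noise_fraction = 0.03, seed = 5))
  expect_identical(simulate_melt(noise_sd = 0.01, seed = 2),
                   simulate_melt(noise_sd = 0.01, seed = 2))
  expect_identical(simulate_sedimentation(noise_sd = 0.002, seed = 9),
                   simulate_sedimentation(noise_sd = 0.002, seed = 9))
})

test_that("noiseless chromatograms evaluate the Gaussian sum exactly", {
  pk <- tibble::tibble(position_ml = c(1.3, 1.5), height = c(0.7, 1),
                       sigma_ml = c(0.05, 0.03))
  ch <- simulate_chromatogram(pk, baseline = 0.1)
  expect_equal(ch$a280,
               0.1 + gaussian_mix(ch$volume_ml, pk$position_ml, pk$height,
                                  pk$sigma_ml))
  expect_error(simulate_chromatogram(pk[0, ]), "non-empty")
  expect_error(simulate_chromatogram(
    tibble::tibble(position_ml = 1.4, height = 1, sigma_ml = -1)), "sigma")
  expect_error(simulate_chromatogram(
    tibble::tibble(position_ml = 3, height = 1, sigma_ml = 0.02)), "positions")
})

test_that("rigid homogeneous relaxation tables match the reference rates", {
  tab <- simulate_relaxation(12, tau_c_ns = 10, field_mhz = 500, s2_core = 1)
  ref <- ref_n15_rigid(10, 500)
  expect_equal(unique(round(tab$r1, 12)), round(ref$r1, 12))
  expect_equal(unique(round(tab$r2, 12)), round(ref$r2, 12))
  expect_equal(unique(round(tab$noe, 12)), round(ref$noe, 12))
  expect_error(simulate_relaxation(10, field_mhz = -1), "field_mhz")
})

test_that("flexible termini depress the hetNOE below the structured cutoff", {
  tab <- simulate_relaxation(50, flexible_termini = 8, s2_core = 0.87)
  expect_true(all(tab$noe[c(1:8, 43:50)] < 0.65))
  expect_true(all(tab$noe[9:42] >= 0.65))
})

test_that("melt curves follow the two-baseline population average", {
  mc <- simulate_melt()
  truth <- attr(mc, "truth")
  fu <- dimer_unfolded_fraction(mc$temperature_k, truth$delta_h_kj,
                                truth$t_m_k, truth$total_monomer_conc)
  manual <- (1 - fu) * (truth$native_baseline[1] +
                          truth$native_baseline[2] * mc$temperature_k) +
    fu * (truth$unfolded_baseline[1] + truth$unfolded_baseline[2] * mc$temperature_k)
  expect_equal(mc$signal, manual)
  # far below the midpoint the signal is the native baseline
  cold <- simulate_melt(temperature_grid = seq(273.15, 340, by = 0.5))
  i <- cold$temperature_k < 280
  native <- 1.0 - 1e-3 * cold$temperature_k[i]
  expect_equal(cold$signal[i], native, tolerance = 1e-4)
  expect_error(simulate_melt(t_m_k = 400), "within the temperature grid")
})

test_that("sedimentation profiles are exponential in r^2 with mass-linear slope", {
  sed <- simulate_sedimentation(speeds_rpm = 20000)
  truth <- attr(sed, "truth")
  # hand-evaluated exponent at one radius
  omega <- 2 * pi * 20000 / 60
  rref <- min(sed$radius_cm)
  r <- sed$radius_cm[40]
  sigma <- truth$molar_mass_da * (1 - truth$vbar_ml_g * truth$density_g_ml) *
    omega^2 / (8.31446261815324e7 * truth$temperature_k)
  expect_equal(sed$conc[40],
               truth$baseline + truth$reference_conc *
                 exp(sigma * (r^2 - rref^2) / 2))
  # omega = 0 is flat
  flat <- sedimentation_profile(seq(6.9, 7.1, 0.01), 12300, 0,
                                reference_conc = 0.4, baseline = 0.02)
  expect_equal(flat, rep(0.42, 21))
  # doubling the mass doubles the ln-slope of (c - baseline) vs r^2/2
  s1 <- simulate_sedimentation(12300, speeds_rpm = 20000)
  s2 <- simulate_sedimentation(24600, speeds_rpm = 20000)
  slope_of <- function(s) {
    coef(lm(log(s$conc - 0.02) ~ I(s$radius_cm^2 / 2)))[2]
  }
  expect_equal(unname(slope_of(s2) / slope_of(s1)), 2, tolerance = 1e-9)
  expect_error(simulate_sedimentation(vbar_ml_g = 1.2), "buoyancy")
})

test_that("hairpin dimers realize the requested angles and round-trip to PDB", {
  d <- simulate_hairpin_dimer(14, interhelix_angle_deg = 30,
                              docking_angle_deg = 85)
  segs <- assign_helices(d, chain = "A")
  expect_equal(nrow(segs), 2)
  ax1 <- fit_helix_axis(oligostate:::.model_coords(
    d, 1, "A", "CA", seq(segs$first_residue[1], segs$last_residue[1])))
  ax2 <- fit_helix_axis(oligostate:::.model_coords(
    d, 1, "A", "CA", seq(segs$first_residue[2], segs$last_residue[2])))
  expect_equal(crossing_angle(ax1$axis, ax2$axis), 30, tolerance = 1 / 30)
  expect_equal(docking_angle(d), 85, tolerance = 2 / 85)

  # parallel limit
  par0 <- simulate_hairpin_dimer(10, interhelix_angle_deg = 0,
                                 docking_angle_deg = 45)
  s0 <- assign_helices(par0, chain = "A")
  a1 <- fit_helix_axis(oligostate:::.model_coords(
    par0, 1, "A", "CA", seq(s0$first_residue[1], s0$last_residue[1])))
  a2 <- fit_helix_axis(oligostate:::.model_coords(
    par0, 1, "A", "CA", seq(s0$first_residue[2], s0$last_residue[2])))
  expect_lt(crossing_angle(a1$axis, a2$axis), 0.5)

  # PDB round trip within format precision
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(d, tmp)
  d2 <- read_structure(tmp)
  expect_equal(nrow(d2), nrow(d))
  expect_lt(max(abs(d$x - d2$x), abs(d$y - d2$y), abs(d$z - d2$z)), 1e-3)

  # impossible packing is rejected
  expect_error(simulate_hairpin_dimer(10, 30, 85, protomer_offset = 1),
               "Impossible geometry")
  # the gap constraint is honoured by the automatic placement
  expect_gte(oligostate:::.min_interchain_dist(
    d[d$chain == "A", ], d[d$chain == "B", ]), 4 - 1e-6)
})
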