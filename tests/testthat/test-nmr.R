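# Relaxation and chemical-shift analysis.

test_that("tau_c inversion is exact in the noiseless rigid limit", {
  for (tc in c(5, 9.9, 14, 20)) {
    for (field in c(500, 800)) {
      tab <- simulate_relaxation(20, tau_c_ns = tc, field_mhz = field,
                                 s2_core = 1)
      est <- estimate_tau_c(tab)
      expect_equal(est$tau_c_ns, tc, tolerance = 0.005)
    }
  }
  # the closed-form shortcut carries its documented small bias
  tab <- simulate_relaxation(20, tau_c_ns = 10, field_mhz = 500, s2_core = 1)
  approx <- estimate_tau_c(tab, method = "approx")
  expect_equal(approx$tau_c_ns, 10, tolerance = 0.02)
})

test_that("tau_c depends only on the R2/R1 ratio", {
  tab <- simulate_relaxation(20, tau_c_ns = 8, field_mhz = 600, s2_core = 1)
  scaled <- tab
  scaled$r1 <- scaled$r1 * 1.7
  scaled$r2 <- scaled$r2 * 1.7
  attr(scaled, "field_mhz") <- 600
  expect_equal(estimate_tau_c(tab)$tau_c_ns, estimate_tau_c(scaled)$tau_c_ns,
               tolerance = 1e-9)
})

test_that("fast-motion residues are rejected at the ratio boundary", {
  # build a table whose first residue sits exactly at 6 R2/R1 = 7
  tab <- simulate_relaxation(10, tau_c_ns = 10, field_mhz = 500, s2_core = 1)
  tab$r2[1] <- tab$r1[1] * 7 / 6
  est <- suppressWarnings(estimate_tau_c(tab, r2_mad_k = 1e9))
  expect_true(1 %in% est$rejected$residue)
  expect_false(1 %in% est$residues_used)
  # all rejected is fatal
  bad <- tibble::tibble(residue = 1:6, r1 = 2, r2 = 2, noe = 0.8)
  attr(bad, "field_mhz") <- 500
  expect_error(estimate_tau_c(bad), "All residues rejected")
})

test_that("exchange sites are excluded by the R2 band and flagged", {
  rex <- setNames(rep(5, 4), c("12", "20", "27", "33"))
  tab <- simulate_relaxation(40, tau_c_ns = 10, field_mhz = 500,
                             s2_core = 1, rex_sites = rex)
  est <- estimate_tau_c(tab)
  expect_true(all(c(12, 20, 27, 33) %in% est$rejected$residue))
  expect_equal(est$tau_c_ns, 10, tolerance = 0.03)
  expect_equal(flag_exchange_broadened(tab), c(12L, 20L, 27L, 33L))
})

test_that("structured-region delineation recovers the rigid core exactly", {
  allhi <- tibble::tibble(residue = 1:20, noe = 0.8)
  r <- structured_region(allhi)
  expect_equal(r$first_residue, 1)
  expect_equal(r$last_residue, 20)

  tab <- simulate_relaxation(55, flexible_termini = 8)
  r <- structured_region(tab)
  expect_equal(nrow(r), 1)
  expect_equal(r$first_residue, 9)
  expect_equal(r$last_residue, 47)
  expect_equal(r$n_residues, 39L)

  # single-residue dips inside a run are tolerated
  dip <- tibble::tibble(residue = 1:12, noe = c(rep(0.8, 5), 0.3, rep(0.8, 6)))
  expect_equal(nrow(structured_region(dip)), 1)
})

test_that("exchange flagging is empty on homogeneous tables and monotone in Rex", {
  flat <- simulate_relaxation(30, s2_core = 1)
  expect_equal(length(flag_exchange_broadened(flat)), 0)
  prev <- integer()
  for (rex in c(2, 4, 8)) {
    tab <- simulate_relaxation(30, s2_core = 1,
                               rex_sites = setNames(rex, "15"))
    got <- flag_exchange_broadened(tab)
    expect_true(all(prev %in% got))
    prev <- got
  }
  expect_equal(prev, 15L)
})

test_that("false-positive rate of the exchange flag stays near the Gaussian tail", {
  hits <- 0; total <- 0
  for (s in 1:200) {
    tab <- simulate_relaxation(40, tau_c_ns = 10, field_mhz = 500,
                               s2_core = 1, noise_fraction = 0.02, seed = s)
    hits <- hits + length(flag_exchange_broadened(tab))
    total <- total + 40
  }
  # one-sided 3-sigma MAD rule on ~normal noise: ~0.13% per residue;
  # allow generous sampling slack
  expect_lt(hits / total, 0.01)
})

test_that("shift dispersion is a translation-invariant range", {
  sh <- tibble::tibble(residue = c(1, 2), atom = c("H", "H"),
                       ppm = c(11.50, 6.90))
  expect_equal(shift_dispersion(sh), 4.6)
  same <- tibble::tibble(residue = 1:5, atom = "H", ppm = rep(8.1, 5))
  expect_equal(shift_dispersion(same), 0)
  shifted <- sh
  shifted$ppm <- shifted$ppm + 0.37
  expect_equal(shift_dispersion(shifted), shift_dispersion(sh))
  expect_error(shift_dispersion(sh, atom = "CA"), "Fewer than 2")
})

test_that("secondary-shift classifier separates helix from coil", {
  rc <- random_coil_shifts()
  mk <- function(resname, residue, dca, dcb) {
    r <- rc[rc$resname == resname, ]
    tibble::tibble(residue = residue, resname = resname,
                   atom = c("CA", "CB"), ppm = c(r$ca + dca, r$cb + dcb))
  }
  coil <- dplyr::bind_rows(lapply(1:8, function(i) mk("ALA", i, 0, 0)))
  expect_true(all(classify_secondary_shifts(coil)$state == "coil"))

  helix <- dplyr::bind_rows(
    lapply(1:4, function(i) mk("LEU", i, 0, 0)),
    lapply(5:14, function(i) mk("LEU", i, 2.6, -0.4)),
    lapply(15:18, function(i) mk("LEU", i, 0, 0)))
  got <- classify_secondary_shifts(helix)
  expect_true(all(got$state[6:13] == "helix"))
  expect_true(all(got$state[c(1:3, 16:18)] == "coil"))
})

test_that("the NMR-STAR shift loop reader extracts residue, atom and value", {
  star <- c(
    "data_test",
    "save_assigned_chemical_shifts",
    "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Seq_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Atom_type",
    "      _Atom_chem_shift.Val",
    "      _Atom_chem_shift.Val_err",
    "      1 41 TYR H  H 10.21 0.02",
    "      2 41 TYR CA C 60.11 0.1",
    "      3 42 LEU H  H  7.85 0.02",
    "   stop_",
    "save_")
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(star, f)
  got <- read_nmrstar_shifts(f)
  expect_equal(nrow(got), 3)
  expect_equal(got$residue, c(41L, 41L, 42L))
  expect_equal(got$atom, c("H", "CA", "H"))
  expect_equal(got$ppm, c(10.21, 60.11, 7.85))
  f2 <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_x", "loop_", "_Other.tag", "1", "stop_"), f2)
  expect_error(read_nmrstar_shifts(f2), "No Atom_chem_shift")
})
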