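# Synthetic-data generators. Each generator evaluates a stated closed form
# exactly in the noiseless limit and is bit-reproducible given a seed, so
# every downstream estimator has a parameter-recovery oracle.

#' Simulate a size-exclusion chromatogram
#'
#' A sum of Gaussian elution peaks on a regular volume grid, plus a constant
#' baseline and iid Gaussian noise. With `noise_sd = 0` the apex of each
#' resolved peak sits exactly at its specified elution volume.
#'
#' @param peaks Data frame with columns `position_ml`, `height`, `sigma_ml`
#'   (one row per peak; all sigmas > 0).
#' @param baseline Constant baseline (AU).
#' @param noise_sd Standard deviation of additive noise (AU).
#' @param volume_grid Numeric vector of volumes (mL), or `c(start, stop,
#'   step)` shorthand when length 3 and increasing.
#' @param vt_ml Total column volume; peak positions must lie in `(0, vt_ml]`.
#' @param seed Integer seed for reproducibility (`NULL` leaves the RNG
#'   stream untouched).
#' @return Tibble with columns `volume_ml`, `a280`.
#' @export
#' @examples
#' chrom <- simulate_chromatogram(
#'   tibble::tibble(position_ml = c(1.27, 1.47), height = c(0.5, 1),
#'                  sigma_ml = 0.02))
#' detect_peaks(chrom)
simulate_chromatogram <- function(peaks, baseline = 0, noise_sd = 0,
                                  volume_grid = c(0.8, 2.4, 0.002),
                                  vt_ml = 2.41, seed = NULL) {
  peaks <- tibble::as_tibble(peaks)
  need <- c("position_ml", "height", "sigma_ml")
  if (!all(need %in% names(peaks)) || nrow(peaks) == 0) {
    rlang::abort("`peaks` must be a non-empty table with position_ml, height, sigma_ml.")
  }
  if (any(peaks$sigma_ml <= 0)) rlang::abort("Peak sigmas must be > 0.")
  if (any(peaks$position_ml <= 0 | peaks$position_ml > vt_ml)) {
    rlang::abort("Peak positions must lie in (0, vt_ml].")
  }
  v <- if (length(volume_grid) == 3 && volume_grid[3] > 0 &&
           volume_grid[3] < diff(volume_grid[1:2])) {
    seq(volume_grid[1], volume_grid[2], by = volume_grid[3])
  } else {
    sort(volume_grid)
  }
  y <- rep(baseline, length(v))
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$height[i] *
      exp(-0.5 * ((v - peaks$position_ml[i]) / peaks$sigma_ml[i])^2)
  }
  if (noise_sd > 0) {
    y <- y + .with_seed(seed, rnorm(length(v), 0, noise_sd))
  }
  tibble::tibble(volume_ml = v, a280 = y)
}

#' Simulate a per-residue 15N relaxation table
#'
#' Generates R1, R2 and hetNOE profiles for a chain tumbling isotropically
#' at `tau_c_ns`, using the same spectral densities as [n15_rates()]. The
#' rigid core carries order parameter `s2_core`; over the `flexible_termini`
#' residues at each end the order parameter ramps linearly down to
#' `s2_terminal` and picks up an effective internal correlation time
#' `tau_e_flex_ps`, emulating disordered tails. Selected residues can
#' receive an exchange contribution to R2. Relative Gaussian noise is added
#' per rate.
#'
#' @param n_residues Chain length.
#' @param tau_c_ns Overall correlation time, ns.
#' @param field_mhz 1H frequency, MHz.
#' @param s2_core Core order parameter.
#' @param flexible_termini Number of flexible residues at each end.
#' @param s2_terminal Order parameter at the outermost residue.
#' @param tau_e_flex_ps Internal correlation time of flexible residues, ps.
#' @param rex_sites Named numeric vector mapping residue number to an Rex
#'   contribution (1/s), e.g. `c("30" = 5)`.
#' @param noise_fraction Relative noise level applied to the rates (see
#'   Details).
#' @param first_residue Number of the first residue.
#' @param seed Integer seed.
#' @details Noise is applied multiplicatively to R1 and R2
#'   (`rate * (1 + eps)`, `eps ~ N(0, noise_fraction)`) and additively to
#'   the NOE with standard deviation `noise_fraction` (the NOE is a ratio
#'   near unity, so a relative and absolute error coincide there).
#' @return Tibble with columns `residue`, `r1`, `r2`, `noe`, carrying the
#'   field in attribute `"field_mhz"` and the full ground-truth parameters
#'   in attribute `"truth"`.
#' @export
#' @examples
#' tab <- simulate_relaxation(60, tau_c_ns = 9.9, field_mhz = 500)
#' estimate_tau_c(tab)
simulate_relaxation <- function(n_residues, tau_c_ns = 9.9, field_mhz = 500,
                                s2_core = 0.87, flexible_termini = 0,
                                s2_terminal = 0.2, tau_e_flex_ps = 1000,
                                rex_sites = NULL, noise_fraction = 0,
                                first_residue = 1L, seed = NULL) {
  if (n_residues < 1) rlang::abort("`n_residues` must be >= 1.")
  .assert_scalar_num(tau_c_ns, "tau_c_ns", positive = TRUE)
  .assert_scalar_num(field_mhz, "field_mhz", positive = TRUE)
  if (s2_core < 0 || s2_core > 1) rlang::abort("`s2_core` must be in [0, 1].")

  res <- seq.int(first_residue, length.out = n_residues)
  s2 <- rep(s2_core, n_residues)
  tau_e <- rep(0, n_residues)
  if (flexible_termini > 0) {
    m <- min(flexible_termini, floor(n_residues / 2))
    # ramp from s2_terminal at the chain end up to the core value
    ramp <- seq(s2_terminal, s2_core, length.out = m + 1)[1:m]
    s2[1:m] <- ramp
    s2[(n_residues - m + 1):n_residues] <- rev(ramp)
    tau_e[c(1:m, (n_residues - m + 1):n_residues)] <- tau_e_flex_ps
  }
  rex <- rep(0, n_residues)
  if (!is.null(rex_sites) && length(rex_sites)) {
    pos <- match(as.integer(names(rex_sites)), res)
    if (anyNA(pos)) rlang::abort("`rex_sites` names must be residue numbers in range.")
    rex[pos] <- as.numeric(rex_sites)
  }
  rates <- n15_rates(tau_c_ns, field_mhz, s2 = s2, tau_e_ps = tau_e,
                     rex_s = rex)
  if (noise_fraction > 0) {
    rates <- .with_seed(seed, {
      n <- n_residues
      dplyr::mutate(rates,
        r1 = .data$r1 * (1 + rnorm(n, 0, noise_fraction)),
        r2 = .data$r2 * (1 + rnorm(n, 0, noise_fraction)),
        noe = .data$noe + rnorm(n, 0, noise_fraction))
    })
  }
  out <- tibble::tibble(residue = res, r1 = rates$r1, r2 = rates$r2,
                        noe = rates$noe)
  attr(out, "field_mhz") <- field_mhz
  attr(out, "truth") <- list(tau_c_ns = tau_c_ns, s2 = s2, tau_e_ps = tau_e,
                             rex_s = rex)
  out
}

#' Simulate a two-state dimer melt curve
#'
#' Signal is a population-weighted average of two linear baselines,
#' `signal = (1 - fU) (aN + bN T) + fU (aU + bU T) + noise`, with the
#' unfolded fraction from [dimer_unfolded_fraction()].
#'
#' @param delta_h_kj Van't Hoff enthalpy, kJ/mol.
#' @param t_m_k Midpoint temperature (K) at `total_monomer_conc`.
#' @param total_monomer_conc Total monomer concentration, M.
#' @param native_baseline,unfolded_baseline Length-2 vectors
#'   `c(intercept, slope)`.
#' @param noise_sd Absolute noise standard deviation (signal units).
#' @param temperature_grid Temperatures (K); must bracket `t_m_k`.
#' @param seed Integer seed.
#' @return Tibble with columns `temperature_k`, `signal`; ground truth in
#'   attribute `"truth"`.
#' @export
simulate_melt <- function(delta_h_kj = 300, t_m_k = 338.15,
                          total_monomer_conc = 20e-6,
                          native_baseline = c(1.0, -1e-3),
                          unfolded_baseline = c(0.1, -2e-4),
                          noise_sd = 0,
                          temperature_grid = seq(293.15, 368.15, by = 0.5),
                          seed = NULL) {
  if (t_m_k < min(temperature_grid) || t_m_k > max(temperature_grid)) {
    rlang::abort("`t_m_k` must lie within the temperature grid.")
  }
  fu <- dimer_unfolded_fraction(temperature_grid, delta_h_kj, t_m_k,
                                total_monomer_conc)
  sig <- (1 - fu) * (native_baseline[1] + native_baseline[2] * temperature_grid) +
    fu * (unfolded_baseline[1] + unfolded_baseline[2] * temperature_grid)
  if (noise_sd > 0) {
    sig <- sig + .with_seed(seed, rnorm(length(sig), 0, noise_sd))
  }
  out <- tibble::tibble(temperature_k = temperature_grid, signal = sig)
  attr(out, "truth") <- list(delta_h_kj = delta_h_kj, t_m_k = t_m_k,
                             total_monomer_conc = total_monomer_conc,
                             native_baseline = native_baseline,
                             unfolded_baseline = unfolded_baseline)
  out
}

#' Simulate sedimentation-equilibrium radial profiles
#'
#' One exponential concentration distribution per rotor speed, from
#' [sedimentation_profile()], with additive Gaussian noise.
#'
#' @param molar_mass_da Molar mass, Da.
#' @param speeds_rpm Rotor speeds in revolutions per minute.
#' @param vbar_ml_g Partial specific volume, mL/g.
#' @param density_g_ml Solvent density, g/mL.
#' @param temperature_k Temperature, K.
#' @param radial_grid Radii (cm).
#' @param reference_conc Concentration at the innermost radius.
#' @param baseline Baseline offset.
#' @param noise_sd Absolute noise standard deviation.
#' @param seed Integer seed.
#' @return Tibble with columns `radius_cm`, `conc`, `speed_rad_s`; ground
#'   truth in attribute `"truth"`.
#' @export
simulate_sedimentation <- function(molar_mass_da = 12300,
                                   speeds_rpm = c(20000, 28000),
                                   vbar_ml_g = 0.73, density_g_ml = 1.0,
                                   temperature_k = 293.15,
                                   radial_grid = seq(6.95, 7.15, length.out = 80),
                                   reference_conc = 0.4, baseline = 0.02,
                                   noise_sd = 0, seed = NULL) {
  .assert_scalar_num(molar_mass_da, "molar_mass_da", positive = TRUE)
  profs <- purrr::map(speeds_rpm, function(rpm) {
    omega <- 2 * pi * rpm / 60
    conc <- sedimentation_profile(
      radial_grid, molar_mass_da, omega, vbar_ml_g, density_g_ml,
      temperature_k, reference_radius_cm = min(radial_grid),
      reference_conc = reference_conc, baseline = baseline)
    tibble::tibble(radius_cm = radial_grid, conc = conc,
                   speed_rad_s = omega)
  })
  out <- dplyr::bind_rows(profs)
  if (noise_sd > 0) {
    out$conc <- out$conc + .with_seed(seed, rnorm(nrow(out), 0, noise_sd))
  }
  attr(out, "truth") <- list(molar_mass_da = molar_mass_da,
                             vbar_ml_g = vbar_ml_g,
                             density_g_ml = density_g_ml,
                             temperature_k = temperature_k,
                             reference_conc = reference_conc,
                             baseline = baseline)
  out
}
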