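# Equilibrium models: two-state dimer <-> unfolded-monomer thermal
# unfolding, and single-species sedimentation equilibrium.

#' Unfolded fraction for a two-state dimer melt
#'
#' For the coupled unfolding/dissociation equilibrium `N2 <-> 2U` at total
#' monomer concentration `Ct`, the mass-action constant is
#' `K = [U]^2/[N2] = 2 Ct fU^2 / (1 - fU)`. The temperature dependence is
#' van't Hoff, `K(T) = K(Tm) exp[-(dH/R)(1/T - 1/Tm)]`, with the midpoint
#' convention `K(Tm) = Ct` so that exactly half of the monomer units are
#' unfolded at `Tm`. The unique positive root of the resulting quadratic is
#' returned. Because the transition is bimolecular, the midpoint shifts with
#' concentration; `t_m_k` is the midpoint *at* `total_monomer_conc`.
#'
#' @param temperature_k Temperature(s), K.
#' @param delta_h_kj Van't Hoff enthalpy of unfolding, kJ per mol of dimer.
#' @param t_m_k Midpoint temperature (K) at `total_monomer_conc`.
#' @param total_monomer_conc Total monomer concentration (mol/L).
#' @return Unfolded fraction in `[0, 1]`, same length as `temperature_k`.
#' @export
#' @examples
#' dimer_unfolded_fraction(338, 300, 338, 20e-6) # 0.5 at the midpoint
dimer_unfolded_fraction <- function(temperature_k, delta_h_kj, t_m_k,
                                    total_monomer_conc) {
  .assert_scalar_num(delta_h_kj, "delta_h_kj", positive = TRUE)
  .assert_scalar_num(t_m_k, "t_m_k", positive = TRUE)
  .assert_scalar_num(total_monomer_conc, "total_monomer_conc", positive = TRUE)
  dh <- delta_h_kj * 1000
  K <- total_monomer_conc *
    exp(-(dh / .R_gas) * (1 / temperature_k - 1 / t_m_k))
  ct <- total_monomer_conc
  # positive root of 2 Ct fU^2 + K fU - K = 0, written in the conjugate
  # form 2K / (K + sqrt(K^2 + 8 Ct K)) to avoid cancellation at small K
  fu <- 2 * K / (K + sqrt(K^2 + 8 * ct * K))
  pmin(pmax(fu, 0), 1)
}

#' Fit a two-state dimer thermal melt
#'
#' Non-linear least squares of
#' `signal = (1 - fU) (aN + bN T) + fU (aU + bU T)` with `fU` given by
#' [dimer_unfolded_fraction()]. Baselines are initialized from the terminal
#' 10% of points, the midpoint from the extremum of the smoothed derivative,
#' and the enthalpy from the transition width (van't Hoff rule of thumb).
#'
#' @param curve Data frame with columns `temperature_k` and `signal`,
#'   covering the transition with at least 20 points.
#' @param total_monomer_conc Total monomer concentration (mol/L), fixed.
#' @return A `dimer_melt_fit` object wrapping the `nls` fit; see
#'   [tidy.dimer_melt_fit()] and [glance.dimer_melt_fit()].
#' @export
fit_dimer_melt <- function(curve, total_monomer_conc) {
  curve <- tibble::as_tibble(curve)
  if (!all(c("temperature_k", "signal") %in% names(curve))) {
    rlang::abort("`curve` needs columns `temperature_k` and `signal`.")
  }
  if (nrow(curve) < 20) rlang::abort("Need >= 20 temperature points.")
  .assert_scalar_num(total_monomer_conc, "total_monomer_conc", positive = TRUE)
  curve <- dplyr::arrange(curve, .data$temperature_k)
  tt <- curve$temperature_k; yy <- curve$signal

  # transition detection and initial values from the smoothed derivative;
  # the smoothing window scales with the grid so that broad dimer melts are
  # separated from point-to-point noise, and the window-length edges (where
  # the shrinking-window mean is biased) are excluded from the peak search
  w <- max(3, 2 * floor(length(tt) / 30) + 1)
  dy <- diff(.rollk(yy, w)) / diff(tt)
  dys <- .rollk(dy, w)
  tmid <- (tt[-1] + tt[-length(tt)]) / 2
  interior <- seq(min(w, length(dys)), max(length(dys) - w + 1, 1))
  dev <- abs(dys - median(dys[interior], na.rm = TRUE))
  peak <- interior[which.max(dev[interior])]
  # derivative noise gauged on the terminal quarters (baseline regions),
  # so a broad transition cannot inflate its own detection threshold
  m <- max(length(interior) %/% 4, 2)
  edges <- c(utils::head(interior, m), utils::tail(interior, m))
  if (dev[peak] < 3 * mad(dys[edges], na.rm = TRUE) + 1e-12) {
    rlang::abort(paste("No melting transition detected;",
                       "consider a baseline-only linear fit."))
  }
  tm0 <- tmid[peak]
  half <- dev >= dev[peak] / 2
  width <- max(diff(range(tmid[half])), 2)
  dh0 <- 6 * .R_gas * tm0^2 / width / 1000 # kJ/mol

  k <- max(3, ceiling(length(tt) * 0.10))
  fn <- lm(yy[1:k] ~ tt[1:k])
  fu <- lm(yy[(length(tt) - k + 1):length(tt)] ~
             tt[(length(tt) - k + 1):length(tt)])

  melt_model <- function(temperature_k, dh, tm, an, bn, au, bu) {
    fu <- dimer_unfolded_fraction(temperature_k, dh, tm, total_monomer_conc)
    (1 - fu) * (an + bn * temperature_k) + fu * (au + bu * temperature_k)
  }
  fit <- minpack.lm::nlsLM(
    signal ~ melt_model(temperature_k, dh, tm, an, bn, au, bu),
    data = curve,
    start = list(dh = unname(dh0), tm = unname(tm0),
                 an = unname(coef(fn)[1]), bn = unname(coef(fn)[2]),
                 au = unname(coef(fu)[1]), bu = unname(coef(fu)[2])),
    lower = c(dh = 1, tm = min(tt), an = -Inf, bn = -Inf, au = -Inf, bu = -Inf),
    upper = c(dh = 5000, tm = max(tt), an = Inf, bn = Inf, au = Inf, bu = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  structure(
    list(fit = fit, curve = curve, total_monomer_conc = total_monomer_conc),
    class = "dimer_melt_fit"
  )
}

#' @export
print.dimer_melt_fit <- function(x, ...) {
  p <- coef(x$fit)
  cat("<dimer_melt_fit>  N2 <-> 2U, van't Hoff\n")
  cat(sprintf("  Tm = %.2f K (%.1f C) at Ct = %.3g M\n",
              p[["tm"]], p[["tm"]] - 273.15, x$total_monomer_conc))
  cat(sprintf("  dH = %.0f kJ/mol\n", p[["dh"]]))
  invisible(x)
}

#' Sedimentation-equilibrium concentration profile
#'
#' Single ideal species at equilibrium in a centrifugal field:
#' `c(r) = baseline + c_ref exp[ sigma (r^2 - r_ref^2) / 2 ]` with reduced
#' buoyant molar mass `sigma = M (1 - vbar rho) omega^2 / (R T)`.
#'
#' @param radius_cm Radial position(s), cm.
#' @param molar_mass_da Molar mass, Da (g/mol).
#' @param omega_rad_s Rotor angular velocity, rad/s.
#' @param vbar_ml_g Partial specific volume, mL/g.
#' @param density_g_ml Solvent density, g/mL.
#' @param temperature_k Temperature, K.
#' @param reference_radius_cm Reference radius, cm.
#' @param reference_conc Concentration (signal) at the reference radius.
#' @param baseline Radially invariant baseline offset.
#' @return Concentration at `radius_cm` (same units as `reference_conc`).
#' @export
sedimentation_profile <- function(radius_cm, molar_mass_da, omega_rad_s,
                                  vbar_ml_g = 0.73, density_g_ml = 1.0,
                                  temperature_k = 293.15,
                                  reference_radius_cm = min(radius_cm),
                                  reference_conc = 1, baseline = 0) {
  .assert_scalar_num(molar_mass_da, "molar_mass_da", positive = TRUE)
  buoy <- 1 - vbar_ml_g * density_g_ml
  if (buoy <= 0 || buoy >= 1) {
    rlang::abort("Need 0 < vbar * density < 1 for a positive buoyancy term.")
  }
  sigma <- .sed_sigma(molar_mass_da, omega_rad_s, vbar_ml_g, density_g_ml,
                      temperature_k)
  baseline + reference_conc *
    exp(sigma * (radius_cm^2 - reference_radius_cm^2) / 2)
}

# reduced buoyant molar mass (cm^-2); cgs: R = 8.314e7 erg / (mol K)
.sed_sigma <- function(m, omega, vbar, rho, temp) {
  m * (1 - vbar * rho) * omega^2 / (8.31446261815324e7 * temp)
}

#' Fit a single-species sedimentation-equilibrium model
#'
#' Global non-linear least squares across one or more radial profiles with a
#' single shared molar mass and a per-profile reference concentration and
#' baseline. The reference concentration is parameterized on the log scale
#' to keep it positive; starting values come from a linearized fit of
#' `ln(c - baseline)` against `r^2/2`.
#'
#' @param profiles Data frame with columns `radius_cm`, `conc` and
#'   `speed_rad_s` (profiles are grouped by rotor speed); at least 20 radial
#'   points per profile.
#' @param vbar_ml_g Partial specific volume, mL/g.
#' @param density_g_ml Solvent density, g/mL.
#' @param temperature_k Temperature, K.
#' @return A `sedeq_fit` object; see [tidy.sedeq_fit()] / [glance.sedeq_fit()].
#' @export
fit_sedimentation <- function(profiles, vbar_ml_g = 0.73, density_g_ml = 1.0,
                              temperature_k = 293.15) {
  profiles <- tibble::as_tibble(profiles)
  need <- c("radius_cm", "conc", "speed_rad_s")
  if (!all(need %in% names(profiles))) {
    rlang::abort("`profiles` needs columns radius_cm, conc, speed_rad_s.")
  }
  profiles <- dplyr::arrange(profiles, .data$speed_rad_s, .data$radius_cm)
  profiles$profile <- as.integer(factor(profiles$speed_rad_s))
  nprof <- max(profiles$profile)
  counts <- table(profiles$profile)
  if (any(counts < 20)) rlang::abort("Each profile needs >= 20 radial points.")

  rref <- min(profiles$radius_cm)
  # linearized initialization per profile
  init <- lapply(split(profiles, profiles$profile), function(d) {
    b0 <- min(d$conc) - 0.05 * diff(range(d$conc))
    y <- log(pmax(d$conc - b0, 1e-12))
    x <- (d$radius_cm^2 - rref^2) / 2
    if (stats::cor(d$radius_cm, d$conc) < 0.5) {
      rlang::warn("Profile is not rising with radius; check the data.")
    }
    f <- lm(y ~ x)
    omega <- d$speed_rad_s[1]
    m0 <- coef(f)[2] / .sed_sigma(1, omega, vbar_ml_g, density_g_ml, temperature_k)
    list(m0 = m0, log_cref = coef(f)[1], baseline = b0)
  })
  m_start <- stats::median(vapply(init, `[[`, numeric(1), "m0"))
  if (m_start <= 0) rlang::abort("Linearized initialization gives non-positive molar mass.")

  speeds <- vapply(split(profiles, profiles$profile),
                   function(d) d$speed_rad_s[1], numeric(1))
  model_fn <- function(par) {
    m <- par[["m"]]
    lc <- par[paste0("log_cref", seq_len(nprof))]
    bl <- par[paste0("baseline", seq_len(nprof))]
    sig <- .sed_sigma(m, speeds[profiles$profile], vbar_ml_g, density_g_ml,
                      temperature_k)
    bl[profiles$profile] +
      exp(lc[profiles$profile] + sig * (profiles$radius_cm^2 - rref^2) / 2)
  }
  par0 <- c(
    m = m_start,
    setNames(vapply(init, `[[`, numeric(1), "log_cref"),
             paste0("log_cref", seq_len(nprof))),
    setNames(vapply(init, `[[`, numeric(1), "baseline"),
             paste0("baseline", seq_len(nprof)))
  )
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(par) profiles$conc - model_fn(par),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  m_hat <- coef(fit)[["m"]]
  if (m_hat <= 0) rlang::abort("Fitted molar mass is non-positive.")
  structure(
    list(fit = fit, profiles = profiles, fitted = model_fn(coef(fit)),
         vbar_ml_g = vbar_ml_g, density_g_ml = density_g_ml,
         temperature_k = temperature_k,
         reference_radius_cm = rref, n_profiles = nprof),
    class = "sedeq_fit"
  )
}

#' @export
print.sedeq_fit <- function(x, ...) {
  cat("<sedeq_fit>  single ideal species\n")
  cat(sprintf("  M = %.0f Da (%d profile%s)\n", coef(x$fit)[["m"]],
              x$n_profiles, if (x$n_profiles > 1) "s" else ""))
  invisible(x)
}
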