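# broom-style tidiers for the fitted objects.

#' Tidy a SEC column calibration
#'
#' @param x A `sec_calibration` object.
#' @param ... Unused.
#' @return One row per fitted line coefficient: `line` (`"mw"`/`"rs"`),
#'   `term`, `estimate`, `std.error`.
#' @export
tidy.sec_calibration <- function(x, ...) {
  one <- function(fit, line) {
    if (is.null(fit)) return(NULL)
    s <- summary(fit)$coefficients
    tibble::tibble(line = line, term = c("intercept", "slope"),
                   estimate = s[, 1], std.error = s[, 2])
  }
  dplyr::bind_rows(one(x$mw_fit, "mw"), one(x$rs_fit, "rs"))
}

#' One-row summary of a SEC column calibration
#'
#' @inheritParams tidy.sec_calibration
#' @return Tibble with `vo_ml`, `vo_fitted`, `vt_ml`, `n_standards`,
#'   `r_squared_mw`, `r_squared_rs`.
#' @export
glance.sec_calibration <- function(x, ...) {
  r2 <- function(fit) if (is.null(fit)) NA_real_ else summary(fit)$r.squared
  tibble::tibble(
    vo_ml = x$vo_ml, vo_fitted = x$vo_fitted, vt_ml = x$vt_ml,
    n_standards = nrow(x$standards),
    r_squared_mw = r2(x$mw_fit), r_squared_rs = r2(x$rs_fit)
  )
}

.tidy_nls <- function(fit) {
  s <- summary(fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' Tidy a two-state dimer melt fit
#'
#' @param x A `dimer_melt_fit` object.
#' @param ... Unused.
#' @return Tibble of parameter estimates and standard errors (`dh` in
#'   kJ/mol, `tm` in K, plus the four baseline coefficients).
#' @export
tidy.dimer_melt_fit <- function(x, ...) .tidy_nls(x$fit)

#' One-row summary of a dimer melt fit
#'
#' @inheritParams tidy.dimer_melt_fit
#' @return Tibble with `t_m_k`, `t_m_c`, `delta_h_kj`, `total_monomer_conc`,
#'   `sigma`, `n`.
#' @export
glance.dimer_melt_fit <- function(x, ...) {
  p <- coef(x$fit)
  tibble::tibble(
    t_m_k = p[["tm"]], t_m_c = p[["tm"]] - 273.15, delta_h_kj = p[["dh"]],
    total_monomer_conc = x$total_monomer_conc,
    sigma = summary(x$fit)$sigma, n = nrow(x$curve)
  )
}

#' Tidy a sedimentation-equilibrium fit
#'
#' @param x A `sedeq_fit` object.
#' @param ... Unused.
#' @return Tibble of parameter estimates and standard errors; `m` is the
#'   shared molar mass (Da).
#' @export
tidy.sedeq_fit <- function(x, ...) .tidy_nls(x$fit)

#' One-row summary of a sedimentation-equilibrium fit
#'
#' @inheritParams tidy.sedeq_fit
#' @return Tibble with `molar_mass_da`, its standard error, `n_profiles`,
#'   `sigma`, `n`.
#' @export
glance.sedeq_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    molar_mass_da = s["m", 1], std_error_da = s["m", 2],
    n_profiles = x$n_profiles,
    sigma = sqrt(x$fit$deviance / (nrow(x$profiles) - length(coef(x$fit)))),
    n = nrow(x$profiles)
  )
}

#' Per-residue correlation times behind a tau_c estimate
#'
#' @param x A `tau_c_estimate` object.
#' @param ... Unused.
#' @return Tibble with `residue` and `tau_c_ns` for every residue used.
#' @export
tidy.tau_c_estimate <- function(x, ...) x$per_residue

#' One-row summary of a tau_c estimate
#'
#' @inheritParams tidy.tau_c_estimate
#' @return Tibble with `tau_c_ns`, `sd_ns`, `n_used`, `n_rejected`,
#'   `field_mhz`, `method`.
#' @export
glance.tau_c_estimate <- function(x, ...) {
  tibble::tibble(
    tau_c_ns = x$tau_c_ns, sd_ns = x$sd_ns,
    n_used = length(x$residues_used), n_rejected = nrow(x$rejected),
    field_mhz = x$field_mhz, method = x$method
  )
}
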