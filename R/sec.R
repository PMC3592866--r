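# Analytical size-exclusion chromatography: column calibration and
# conversion of elution volumes into apparent molecular weights, Stokes
# radii, aggregation numbers and oligomeric-state calls.

#' Partition coefficient of a species on a size-exclusion column
#'
#' Computes `Kav = (Ve - Vo) / (Vt - Vo)` for an elution volume `ve_ml` on a
#' column of void volume `vo_ml` and total volume `vt_ml`. `Kav` is 0 for a
#' species excluded from the matrix (eluting at the void) and 1 for one that
#' fully permeates it.
#'
#' @param ve_ml Elution volume (mL). Vectorized.
#' @param vo_ml Column void volume (mL).
#' @param vt_ml Total column volume (mL).
#' @param clamp If `TRUE` (default), values slightly outside `[0, 1]` caused
#'   by apex-interpolation jitter are clamped with a warning instead of
#'   raising an error.
#' @return Dimensionless `Kav`, same length as `ve_ml`.
#' @export
#' @examples
#' compute_kav(1.40, vo_ml = 0.95, vt_ml = 2.41)
compute_kav <- function(ve_ml, vo_ml, vt_ml, clamp = TRUE) {
  .assert_scalar_num(vo_ml, "vo_ml", positive = TRUE)
  .assert_scalar_num(vt_ml, "vt_ml", positive = TRUE)
  if (vo_ml >= vt_ml) rlang::abort("Void volume must be smaller than total volume.")
  kav <- (ve_ml - vo_ml) / (vt_ml - vo_ml)
  bad_lo <- kav < 0
  bad_hi <- kav > 1
  if (any(bad_lo | bad_hi, na.rm = TRUE)) {
    if (!clamp) {
      off <- if (any(bad_lo, na.rm = TRUE)) {
        sprintf("Ve = %.3f mL is below the void volume (%.3f mL)",
                ve_ml[which(bad_lo)[1]], vo_ml)
      } else {
        sprintf("Ve = %.3f mL exceeds the total volume (%.3f mL)",
                ve_ml[which(bad_hi)[1]], vt_ml)
      }
      rlang::abort(paste0("Elution volume out of column range: ", off, "."))
    }
    rlang::warn("Kav outside [0, 1]; clamping (apex jitter?).")
    kav <- pmin(pmax(kav, 0), 1)
  }
  kav
}

# calibration abscissa: x = sqrt(-log10(Kav)); undefined at Kav = 0
.sec_x <- function(ve_ml, vo_ml, vt_ml) {
  kav <- (ve_ml - vo_ml) / (vt_ml - vo_ml)
  if (any(kav <= 0 | kav > 1)) {
    rlang::abort("Standards must elute strictly between the void and total volumes.")
  }
  sqrt(-log10(kav))
}

#' Calibrate a size-exclusion column
#'
#' Fits the two linear calibration lines used to interpret analytical SEC:
#' `Mr^(1/3)` against `x = (-log10 Kav)^(1/2)` (molecular-weight line) and
#' `Rs` against the same abscissa (Stokes-radius line). Either line is
#' fitted whenever the corresponding column is present in `standards`.
#'
#' When the void volume is unknown it is treated as a fit parameter: a fine
#' 1-D scan over `vo_bounds` (by default 0.3-0.6 of the total volume, capped
#' just below the earliest standard) picks the value minimizing the summed
#' squared residuals of the fitted lines, each line's contribution normalized
#' by the variance of its response so that the two are commensurate.
#'
#' @param standards Data frame of calibration standards with columns `ve_ml`
#'   and at least one of `mr_da` (molar mass, Da) and `rs_angstrom` (Stokes
#'   radius). At least two standards are required per fitted line.
#' @param vt_ml Total column volume (mL).
#' @param vo_ml Void volume (mL), if known. When `NULL` it is fitted.
#' @param vo_bounds Search interval for the void-volume scan, as fractions
#'   of `vt_ml`.
#' @return An object of class `sec_calibration`: the column geometry, both
#'   line fits (where available), the calibration domain, and the standards.
#' @seealso [estimate_amw()], [estimate_rs()], [tidy.sec_calibration()]
#' @export
#' @examples
#' std <- tibble::tibble(ve_ml = c(1.27, 1.40, 1.42, 1.57),
#'                       rs_angstrom = c(54, 44, 42, 32))
#' cal <- fit_sec_calibration(std, vt_ml = 2.41)
#' estimate_rs(cal, 1.50)
fit_sec_calibration <- function(standards, vt_ml, vo_ml = NULL,
                                vo_bounds = c(0.3, 0.6)) {
  standards <- tibble::as_tibble(standards)
  .assert_scalar_num(vt_ml, "vt_ml", positive = TRUE)
  if (!"ve_ml" %in% names(standards)) {
    rlang::abort("`standards` must have a `ve_ml` column.")
  }
  has_mw <- "mr_da" %in% names(standards) && sum(!is.na(standards$mr_da)) >= 2
  has_rs <- "rs_angstrom" %in% names(standards) &&
    sum(!is.na(standards$rs_angstrom)) >= 2
  if (!has_mw && !has_rs) {
    rlang::abort("Need >= 2 standards with `mr_da` and/or `rs_angstrom`.")
  }

  fit_lines <- function(vo) {
    out <- list(mw = NULL, rs = NULL, score = 0)
    if (has_mw) {
      d <- standards[!is.na(standards$mr_da), ]
      x <- .sec_x(d$ve_ml, vo, vt_ml)
      if (diff(range(x)) < 1e-12) rlang::abort("All standards share one Kav; singular fit.")
      y <- d$mr_da^(1 / 3)
      f <- lm(y ~ x)
      out$mw <- f
      out$score <- out$score + sum(resid(f)^2) / stats::var(y)
    }
    if (has_rs) {
      d <- standards[!is.na(standards$rs_angstrom), ]
      x <- .sec_x(d$ve_ml, vo, vt_ml)
      if (diff(range(x)) < 1e-12) rlang::abort("All standards share one Kav; singular fit.")
      y <- d$rs_angstrom
      f <- lm(y ~ x)
      out$rs <- f
      out$score <- out$score + sum(resid(f)^2) / stats::var(y)
    }
    out
  }

  vo_fitted <- is.null(vo_ml)
  if (vo_fitted) {
    lo <- vo_bounds[1] * vt_ml
    hi <- min(vo_bounds[2] * vt_ml, min(standards$ve_ml) - 0.02)
    if (hi <= lo) rlang::abort("No admissible void volume inside `vo_bounds`.")
    grid <- seq(lo, hi, length.out = 400L)
    scores <- vapply(grid, function(v) fit_lines(v)$score, numeric(1))
    vo_ml <- grid[which.min(scores)]
  } else {
    .assert_scalar_num(vo_ml, "vo_ml", positive = TRUE)
    if (vo_ml >= min(standards$ve_ml)) {
      rlang::abort("Void volume must precede every standard's elution volume.")
    }
  }

  fits <- fit_lines(vo_ml)
  # slope-sign sanity: earlier elution (larger x) must mean larger species
  for (nm in c("mw", "rs")) {
    if (!is.null(fits[[nm]]) && coef(fits[[nm]])[2] < 0) {
      rlang::warn(sprintf(
        "%s calibration slope is negative; larger species should elute earlier.",
        toupper(nm)))
    }
  }

  structure(
    list(
      vo_ml = vo_ml, vt_ml = vt_ml, vo_fitted = vo_fitted,
      mw_fit = fits$mw, rs_fit = fits$rs,
      ve_domain = range(standards$ve_ml),
      standards = standards
    ),
    class = "sec_calibration"
  )
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat("<sec_calibration>\n")
  cat(sprintf("  column: Vo = %.3f mL%s, Vt = %.2f mL\n", x$vo_ml,
              if (x$vo_fitted) " (fitted)" else "", x$vt_ml))
  if (!is.null(x$mw_fit)) {
    cat(sprintf("  Mr^(1/3) line: intercept %.3f, slope %.3f (Da^1/3)\n",
                coef(x$mw_fit)[1], coef(x$mw_fit)[2]))
  }
  if (!is.null(x$rs_fit)) {
    cat(sprintf("  Rs line: intercept %.2f, slope %.2f (Angstrom)\n",
                coef(x$rs_fit)[1], coef(x$rs_fit)[2]))
  }
  cat(sprintf("  calibration domain: %.2f-%.2f mL (%d standards)\n",
              x$ve_domain[1], x$ve_domain[2], nrow(x$standards)))
  invisible(x)
}

.cal_predict <- function(cal, ve_ml, which) {
  fit <- cal[[paste0(which, "_fit")]]
  if (is.null(fit)) {
    rlang::abort(sprintf("Calibration has no %s line (standards lacked the column).",
                         toupper(which)))
  }
  outside <- ve_ml < cal$ve_domain[1] | ve_ml > cal$ve_domain[2]
  if (any(outside)) {
    rlang::warn(sprintf("Extrapolating beyond the calibration domain (%.2f-%.2f mL).",
                        cal$ve_domain[1], cal$ve_domain[2]))
  }
  x <- .sec_x(ve_ml, cal$vo_ml, cal$vt_ml)
  as.numeric(coef(fit)[1] + coef(fit)[2] * x)
}

#' Apparent molecular weight from a column calibration
#'
#' Evaluates the `Mr^(1/3)`-vs-`(-log10 Kav)^(1/2)` line at an elution
#' volume and cubes the result. Warns when `ve_ml` lies outside the span of
#' the calibration standards.
#'
#' @param cal A [fit_sec_calibration()] object with a molecular-weight line.
#' @param ve_ml Elution volume (mL). Vectorized.
#' @return Apparent molecular weight (Da).
#' @export
estimate_amw <- function(cal, ve_ml) {
  y <- .cal_predict(cal, ve_ml, "mw")
  if (any(y <= 0)) rlang::abort("Calibration predicts a negative Mr^(1/3); out of range.")
  y^3
}

#' Apparent Stokes radius from a column calibration
#'
#' Evaluates the `Rs`-vs-`(-log10 Kav)^(1/2)` calibration line at an elution
#' volume.
#'
#' @inheritParams estimate_amw
#' @return Apparent Stokes radius (Angstrom).
#' @export
estimate_rs <- function(cal, ve_ml) {
  y <- .cal_predict(cal, ve_ml, "rs")
  if (any(y <= 0)) rlang::abort("Calibration predicts a negative Stokes radius; out of range.")
  y
}

#' Predicted Stokes radius of a folded globular protein
#'
#' Log-linear predictor `log10(Rs/A) = -0.204 + 0.357 log10(Mr/Da)` for a
#' compact, globular chain.
#'
#' @param mr_da Molar mass (Da). Vectorized.
#' @return Stokes radius (Angstrom).
#' @export
#' @examples
#' predict_rs_folded(12300) # folded QUA1 dimer, ~18 A
predict_rs_folded <- function(mr_da) {
  if (any(mr_da <= 0)) rlang::abort("`mr_da` must be > 0.")
  10^(-0.204 + 0.357 * log10(mr_da))
}

#' Predicted Stokes radius of an unfolded protein
#'
#' Log-linear predictor `log10(Rs/A) = -0.551 + 0.493 log10(Mr/Da)` for a
#' highly expanded, unfolded chain.
#'
#' @inheritParams predict_rs_folded
#' @return Stokes radius (Angstrom).
#' @export
#' @examples
#' predict_rs_unfolded(6150) # unfolded QUA1 monomer, ~21 A
predict_rs_unfolded <- function(mr_da) {
  if (any(mr_da <= 0)) rlang::abort("`mr_da` must be > 0.")
  10^(-0.551 + 0.493 * log10(mr_da))
}

#' Apparent aggregation number
#'
#' Ratio of the SEC-derived apparent molecular weight to the monomer mass.
#' Full precision is returned; displays conventionally round to one decimal.
#'
#' @param amw_da Apparent molecular weight (Da).
#' @param monomer_mass_da Monomer molar mass (Da).
#' @return Dimensionless aggregation number.
#' @export
#' @examples
#' compute_aan(131000, 48000) # ~2.7, a dimer with some shape excess
compute_aan <- function(amw_da, monomer_mass_da) {
  if (any(amw_da <= 0) || any(monomer_mass_da <= 0)) {
    rlang::abort("Masses must be > 0.")
  }
  amw_da / monomer_mass_da
}

#' Classify an oligomeric state from an aggregation number
#'
#' Maps an apparent aggregation number onto a coarse state call. The default
#' band edges (1.35, 2.25, 3.6) assign: monomer below 1.35; monomer/dimer
#' mixture up to 2.25; dimer up to 3.6; higher-order beyond. SEC aggregation
#' numbers routinely exceed the true stoichiometry because elongated fusion
#' proteins deviate from the rigid-sphere calibration, which is why the dimer
#' band extends well past 2.
#'
#' @param aan Aggregation number(s).
#' @param bands Increasing numeric vector of three band edges.
#' @return Factor with levels `monomer`, `monomer/dimer`, `dimer`,
#'   `higher-order`.
#' @export
#' @examples
#' classify_oligomer(c(1.2, 1.7, 2.7, 4.8))
classify_oligomer <- function(aan, bands = c(1.35, 2.25, 3.6)) {
  if (any(aan <= 0)) rlang::abort("`aan` must be > 0.")
  if (length(bands) != 3 || is.unsorted(bands)) {
    rlang::abort("`bands` must be three increasing band edges.")
  }
  cut(aan, breaks = c(0, bands, Inf),
      labels = c("monomer", "monomer/dimer", "dimer", "higher-order"),
      right = FALSE)
}

#' Dimer fraction of an unresolved monomer/dimer mixture
#'
#' For a mixture whose single merged elution peak moves linearly between the
#' monomer and dimer end-member positions, the dimer fraction is estimated in
#' Stokes-radius space as `(Rs_obs - Rs_monomer) / (Rs_dimer - Rs_monomer)`,
#' clipped to `[0, 1]` with a warning.
#'
#' @param rs_obs Observed apparent Stokes radius (Angstrom). Vectorized.
#' @param rs_monomer,rs_dimer End-member Stokes radii (Angstrom);
#'   `rs_dimer` must exceed `rs_monomer`.
#' @return Dimer fraction in `[0, 1]`.
#' @export
#' @examples
#' estimate_dimer_fraction(36.8, rs_monomer = 32, rs_dimer = 44)
estimate_dimer_fraction <- function(rs_obs, rs_monomer = 32, rs_dimer = 44) {
  .assert_scalar_num(rs_monomer, "rs_monomer", positive = TRUE)
  .assert_scalar_num(rs_dimer, "rs_dimer", positive = TRUE)
  if (rs_dimer <= rs_monomer) rlang::abort("`rs_dimer` must exceed `rs_monomer`.")
  f <- (rs_obs - rs_monomer) / (rs_dimer - rs_monomer)
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    rlang::warn("Dimer fraction outside [0, 1]; clipping.")
    f <- pmin(pmax(f, 0), 1)
  }
  f
}

#' Locate elution peaks in a chromatogram
#'
#' Finds local maxima above a relative height threshold and refines each
#' apex by three-point parabolic interpolation, the usual treatment for a
#' sampled A280 trace.
#'
#' @param chrom Data frame with columns `volume_ml` and `a280` (at least five
#'   grid points).
#' @param min_rel_height Minimum peak height, as a fraction of the largest
#'   baseline-subtracted signal, for a maximum to count as a peak.
#' @return Tibble with columns `ve_ml` and `height` (baseline-subtracted),
#'   ordered by elution volume. Empty (with a warning) when nothing clears
#'   the threshold.
#' @export
detect_peaks <- function(chrom, min_rel_height = 0.05) {
  chrom <- tibble::as_tibble(chrom)
  if (!all(c("volume_ml", "a280") %in% names(chrom))) {
    rlang::abort("`chrom` needs columns `volume_ml` and `a280`.")
  }
  if (nrow(chrom) < 5) rlang::abort("Need at least 5 grid points.")
  chrom <- dplyr::arrange(chrom, .data$volume_ml)
  v <- chrom$volume_ml; y <- chrom$a280
  base <- min(y)
  span <- max(y) - base
  n <- length(y)
  i <- 2:(n - 1)
  is_max <- y[i] > y[i - 1] & y[i] >= y[i + 1] &
    (y[i] - base) >= min_rel_height * span
  idx <- i[is_max]
  if (length(idx) == 0 || span == 0) {
    rlang::warn("No peak above threshold.")
    return(tibble::tibble(ve_ml = numeric(), height = numeric()))
  }
  refine <- function(j) {
    y0 <- y[j - 1]; y1 <- y[j]; y2 <- y[j + 1]
    denom <- y0 - 2 * y1 + y2
    delta <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / denom
    delta <- max(min(delta, 0.5), -0.5)
    h <- v[j + 1] - v[j]
    c(v[j] + delta * h, y1 - 0.25 * (y0 - y2) * delta - base)
  }
  out <- t(vapply(idx, refine, numeric(2)))
  tibble::tibble(ve_ml = out[, 1], height = out[, 2])
}
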