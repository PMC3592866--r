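# ggplot2 diagnostics.

#' Plot a chromatogram with detected peaks
#'
#' @param chrom Tibble with `volume_ml`, `a280`.
#' @param peaks Optional peak table from [detect_peaks()]; detected
#'   automatically when `NULL`.
#' @return A ggplot object.
#' @export
plot_chromatogram <- function(chrom, peaks = NULL) {
  peaks <- peaks %||% suppressWarnings(detect_peaks(chrom))
  p <- ggplot2::ggplot(chrom, ggplot2::aes(.data$volume_ml, .data$a280)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Elution volume (mL)", y = "A280 (AU)")
  if (nrow(peaks)) {
    p <- p + ggplot2::geom_vline(
      data = peaks, ggplot2::aes(xintercept = .data$ve_ml),
      linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot per-residue relaxation profiles
#'
#' R1, R2 and hetNOE against residue number, faceted.
#'
#' @param table Relaxation tibble (`residue`, `r1`, `r2`, `noe`).
#' @return A ggplot object.
#' @export
plot_relaxation <- function(table) {
  long <- tidyr::pivot_longer(tibble::as_tibble(table),
                              dplyr::any_of(c("r1", "r2", "noe")),
                              names_to = "parameter", values_to = "value")
  long$parameter <- factor(long$parameter, levels = c("r1", "r2", "noe"),
                           labels = c("R1 (1/s)", "R2 (1/s)", "hetNOE"))
  ggplot2::ggplot(long, ggplot2::aes(.data$residue, .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$parameter),
                        scales = "free_y") +
    ggplot2::labs(x = "Residue", y = NULL)
}

#' @describeIn fit_sec_calibration Calibration plot: standards and fitted
#'   line(s) on the transformed axes.
#' @param object A `sec_calibration` object.
#' @param ... Unused.
#' @export
autoplot.sec_calibration <- function(object, ...) {
  std <- object$standards
  std$x <- .sec_x(std$ve_ml, object$vo_ml, object$vt_ml)
  long <- dplyr::bind_rows(
    if (!is.null(object$mw_fit) && "mr_da" %in% names(std)) {
      tibble::tibble(x = std$x, y = std$mr_da^(1 / 3), line = "Mr^(1/3)")
    },
    if (!is.null(object$rs_fit) && "rs_angstrom" %in% names(std)) {
      tibble::tibble(x = std$x, y = std$rs_angstrom, line = "Rs (A)")
    }
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$line), scales = "free_y") +
    ggplot2::labs(x = expression(sqrt(-log[10] * K[av])), y = NULL)
}

#' @describeIn fit_dimer_melt Melt curve with the fitted two-state model
#'   and baselines.
#' @param object A `dimer_melt_fit` object.
#' @param ... Unused.
#' @export
autoplot.dimer_melt_fit <- function(object, ...) {
  d <- object$curve
  p <- coef(object$fit)
  tt <- seq(min(d$temperature_k), max(d$temperature_k), length.out = 300)
  fu <- dimer_unfolded_fraction(tt, p[["dh"]], p[["tm"]],
                                object$total_monomer_conc)
  fit <- tibble::tibble(
    temperature_k = tt,
    signal = (1 - fu) * (p[["an"]] + p[["bn"]] * tt) +
      fu * (p[["au"]] + p[["bu"]] * tt)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$temperature_k, .data$signal)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = fit, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = p[["tm"]], linetype = "dashed") +
    ggplot2::labs(x = "Temperature (K)", y = "Signal")
}

#' @describeIn fit_sedimentation Radial profiles with the fitted
#'   single-species model.
#' @param object A `sedeq_fit` object.
#' @param ... Unused.
#' @export
autoplot.sedeq_fit <- function(object, ...) {
  d <- object$profiles
  d$fitted <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(.data$radius_cm, .data$conc,
                                  colour = factor(round(.data$speed_rad_s)))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "Radius (cm)", y = "Concentration",
                  colour = "omega (rad/s)")
}
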