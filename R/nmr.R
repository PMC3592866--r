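# Backbone 15N relaxation analysis: model-free rates, overall rotational
# correlation time, structured-region delineation, exchange broadening,
# chemical-shift dispersion and a simple carbon secondary-shift classifier.

#' Model-free 15N relaxation rates for isotropic tumbling
#'
#' Computes R1, R2 and the heteronuclear NOE for a backbone amide 15N spin
#' from the standard dipolar + CSA spectral densities under the Lipari-Szabo
#' model-free form with isotropic overall tumbling:
#' `J(w) = (2/5) [ S2 tau_c / (1 + (w tau_c)^2) + (1 - S2) tau' / (1 + (w tau')^2) ]`
#' with `1/tau' = 1/tau_c + 1/tau_e`. Conformational exchange adds to R2
#' only. All physical constants come from [relaxation_constants()].
#'
#' @param tau_c_ns Overall rotational correlation time, ns.
#' @param field_mhz 1H spectrometer frequency, MHz.
#' @param s2 Generalized order parameter(s) in `[0, 1]`.
#' @param tau_e_ps Effective internal correlation time(s), ps (0 = none).
#' @param rex_s Exchange contribution(s) to R2, 1/s.
#' @return Tibble with columns `r1`, `r2` (1/s) and `noe` (intensity ratio),
#'   one row per element of the vectorized arguments.
#' @export
#' @examples
#' n15_rates(9.9, 500)
n15_rates <- function(tau_c_ns, field_mhz, s2 = 1, tau_e_ps = 0, rex_s = 0) {
  .assert_scalar_num(field_mhz, "field_mhz", positive = TRUE)
  if (any(tau_c_ns <= 0)) rlang::abort("`tau_c_ns` must be > 0.")
  if (any(s2 < 0 | s2 > 1)) rlang::abort("`s2` must lie in [0, 1].")
  k <- relaxation_constants()
  wh <- 2 * pi * field_mhz * 1e6
  wn <- wh * k$gamma_n / k$gamma_h # signed
  d2 <- (k$mu0 / (4 * pi) * k$hbar * k$gamma_h * k$gamma_n / k$r_nh^3)^2 / 4
  c2 <- (wn * k$csa)^2 / 3

  n <- max(length(tau_c_ns), length(s2), length(tau_e_ps), length(rex_s))
  tau_c <- rep_len(tau_c_ns, n) * 1e-9
  s2 <- rep_len(s2, n)
  tau_e <- rep_len(tau_e_ps, n) * 1e-12
  rex <- rep_len(rex_s, n)

  Jw <- function(w) {
    tp <- ifelse(tau_e > 0, 1 / (1 / tau_c + 1 / tau_e), 0)
    0.4 * (s2 * tau_c / (1 + (w * tau_c)^2) +
             (1 - s2) * tp / (1 + (w * tp)^2))
  }
  r1 <- d2 * (Jw(wh - wn) + 3 * Jw(wn) + 6 * Jw(wh + wn)) + c2 * Jw(wn)
  r2 <- 0.5 * d2 * (4 * Jw(0) + Jw(wh - wn) + 3 * Jw(wn) +
                      6 * Jw(wh) + 6 * Jw(wh + wn)) +
    (c2 / 6) * (4 * Jw(0) + 3 * Jw(wn)) + rex
  noe <- 1 + d2 * (k$gamma_h / k$gamma_n) * (6 * Jw(wh + wn) - Jw(wh - wn)) / r1
  tibble::tibble(r1 = r1, r2 = r2, noe = noe)
}

# rigid-rotor R2/R1 ratio as a function of tau_c (ns); monotone increasing
.rigid_ratio <- function(tau_c_ns, field_mhz) {
  r <- n15_rates(tau_c_ns, field_mhz)
  r$r2 / r$r1
}

#' Overall rotational correlation time from R2/R1
#'
#' Estimates the overall rotational correlation time of an isotropically
#' tumbling molecule from per-residue R2/R1 ratios. Residues reporting on
#' internal motion or exchange are excluded first: the heteronuclear NOE
#' must reach `noe_min` (default 0.65) and R2 must lie within
#' `r2_mad_k` median absolute deviations of the median R2 of the retained
#' set. Each surviving ratio is inverted to a per-residue correlation time
#' by root-finding on the exact rigid-rotor ratio curve (method
#' `"exact"`), or with the closed-form large-tau approximation
#' `tau_c = (1/(4 pi nuN)) sqrt(6 R2/R1 - 7)` (method `"approx"`); the
#' closed form always provides the starting bracket. Residues with
#' `6 R2/R1 - 7 <= 0` tumble too fast to carry overall-tumbling information
#' and are rejected rather than fatal.
#'
#' @param table Data frame with columns `residue`, `r1`, `r2` and
#'   (preferably) `noe`.
#' @param field_mhz 1H frequency, MHz; defaults to the `field_mhz` attribute
#'   left by [simulate_relaxation()].
#' @param noe_min NOE cutoff selecting well-structured residues.
#' @param r2_mad_k Half-width of the R2 acceptance band in MADs.
#' @param trim Trim fraction for the trimmed mean.
#' @param method `"exact"` (default) or `"approx"`.
#' @return A `tau_c_estimate` object: `tau_c_ns`, `sd_ns`, the residues used
#'   and a table of rejected residues with reasons.
#' @export
estimate_tau_c <- function(table, field_mhz = attr(table, "field_mhz"),
                           noe_min = 0.65, r2_mad_k = 1.5, trim = 0.1,
                           method = c("exact", "approx")) {
  method <- match.arg(method)
  table <- tibble::as_tibble(table)
  if (is.null(field_mhz)) rlang::abort("Supply `field_mhz`.")
  .assert_scalar_num(field_mhz, "field_mhz", positive = TRUE)
  if (!all(c("residue", "r1", "r2") %in% names(table))) {
    rlang::abort("`table` needs columns residue, r1, r2.")
  }
  if (any(table$r1 <= 0 | table$r2 <= 0, na.rm = TRUE)) {
    rlang::abort("R1 and R2 must be positive.")
  }
  if ("noe" %in% names(table) &&
      any(table$noe < -4 | table$noe > 1.2, na.rm = TRUE)) {
    rlang::warn("hetNOE outside the physical 15N range [-4, 1.2].")
  }
  d <- table[stats::complete.cases(table[, c("residue", "r1", "r2")]), ]
  if (nrow(d) < 5) rlang::abort("Need >= 5 usable residues.")

  rejected <- tibble::tibble(residue = integer(), reason = character())
  if ("noe" %in% names(d)) {
    flex <- d$noe < noe_min
    rejected <- dplyr::bind_rows(rejected, tibble::tibble(
      residue = d$residue[flex], reason = "low hetNOE (internal motion)"))
    d <- d[!flex, ]
  }
  med <- median(d$r2)
  madv <- mad(d$r2)
  # tolerance keeps a perfectly homogeneous (noiseless) core intact while
  # still excluding outliers when the MAD collapses to zero
  out <- abs(d$r2 - med) > r2_mad_k * madv + 1e-9 * med
  out[is.na(out)] <- FALSE
  rejected <- dplyr::bind_rows(rejected, tibble::tibble(
    residue = d$residue[out], reason = "R2 outside median band (exchange?)"))
  d <- d[!out, ]
  ratio <- d$r2 / d$r1
  disc <- 6 * ratio - 7
  fast <- disc <= 0
  rejected <- dplyr::bind_rows(rejected, tibble::tibble(
    residue = d$residue[fast], reason = "6 R2/R1 - 7 <= 0 (fast motion)"))
  d <- d[!fast, ]; ratio <- ratio[!fast]; disc <- disc[!fast]
  if (nrow(d) == 0) rlang::abort("All residues rejected; cannot estimate tau_c.")

  k <- relaxation_constants()
  nu_n <- field_mhz * 1e6 * abs(k$gamma_n) / k$gamma_h
  tau_approx <- 1 / (4 * pi * nu_n) * sqrt(disc) * 1e9

  tau <- if (method == "approx") tau_approx else {
    vapply(seq_along(ratio), function(i) {
      f <- function(t) .rigid_ratio(t, field_mhz) - ratio[i]
      lo <- max(tau_approx[i] / 4, 1e-3)
      hi <- max(tau_approx[i] * 4, 1)
      if (f(lo) > 0 || f(hi) < 0) return(tau_approx[i])
      uniroot(f, c(lo, hi), tol = 1e-6)$root
    }, numeric(1))
  }

  structure(
    list(
      tau_c_ns = mean(tau, trim = trim),
      sd_ns = sd(tau),
      per_residue = tibble::tibble(residue = d$residue, tau_c_ns = tau),
      residues_used = d$residue,
      rejected = rejected,
      field_mhz = field_mhz,
      method = method
    ),
    class = "tau_c_estimate"
  )
}

#' @export
print.tau_c_estimate <- function(x, ...) {
  cat(sprintf("<tau_c_estimate>  tau_c = %.2f +/- %.2f ns (%d residues, %s inversion at %.0f MHz)\n",
              x$tau_c_ns, x$sd_ns, length(x$residues_used), x$method, x$field_mhz))
  if (nrow(x$rejected)) {
    cat(sprintf("  rejected %d residue(s)\n", nrow(x$rejected)))
  }
  invisible(x)
}

#' Delineate the structured region from hetNOE values
#'
#' Returns maximal runs of at least `min_len` residues whose heteronuclear
#' NOE reaches `noe_threshold`, tolerating single-residue dips inside a run.
#' Low NOE values flag sub-nanosecond backbone flexibility, so the
#' complement of these runs is the mobile termini/loops.
#'
#' @param table Data frame with columns `residue` and `noe`.
#' @param noe_threshold NOE cutoff (default 0.65).
#' @param min_len Minimum run length in residues.
#' @return Tibble with columns `first_residue`, `last_residue`, `n_residues`.
#' @export
structured_region <- function(table, noe_threshold = 0.65, min_len = 5) {
  table <- tibble::as_tibble(table)
  if (!all(c("residue", "noe") %in% names(table))) {
    rlang::abort("`table` needs columns residue and noe.")
  }
  table <- dplyr::arrange(table, .data$residue)
  runs <- .runs_with_gaps(table$noe >= noe_threshold, min_len)
  tibble::tibble(
    first_residue = table$residue[runs$start],
    last_residue = table$residue[runs$end],
    n_residues = runs$end - runs$start + 1L
  )
}

#' Flag exchange-broadened residues
#'
#' Within the structured region (hetNOE >= `noe_threshold`), residues whose
#' transverse rate exceeds the structured-region median by more than
#' `k` median absolute deviations are flagged as broadened by
#' millisecond-timescale conformational exchange.
#'
#' @param table Data frame with columns `residue`, `r2` and `noe`.
#' @param k Outlier threshold in MADs (default 3).
#' @param noe_threshold NOE cutoff defining the structured set.
#' @return Integer vector of flagged residue numbers.
#' @export
flag_exchange_broadened <- function(table, k = 3, noe_threshold = 0.65) {
  table <- tibble::as_tibble(table)
  if (!all(c("residue", "r2", "noe") %in% names(table))) {
    rlang::abort("`table` needs columns residue, r2 and noe.")
  }
  s <- table[table$noe >= noe_threshold & !is.na(table$noe), ]
  if (nrow(s) < 10) rlang::abort("Need >= 10 structured residues.")
  med <- median(s$r2)
  madv <- mad(s$r2)
  sort(s$residue[s$r2 - med > k * (madv + .Machine$double.eps)])
}

#' Chemical-shift dispersion
#'
#' Max-minus-min spread of the selected shifts, conventionally quoted for
#' backbone amide protons, where a spread well beyond ~0.8 ppm distinguishes
#' a folded protein from a random coil.
#'
#' @param shifts Data frame with columns `residue`, `atom`, `ppm`.
#' @param atom Atom name to select (default `"H"`, the backbone amide
#'   proton; `"HN"` is accepted as a synonym).
#' @return Dispersion in ppm.
#' @export
shift_dispersion <- function(shifts, atom = "H") {
  shifts <- tibble::as_tibble(shifts)
  if (!all(c("atom", "ppm") %in% names(shifts))) {
    rlang::abort("`shifts` needs columns atom and ppm.")
  }
  sel <- if (atom %in% c("H", "HN")) shifts$atom %in% c("H", "HN")
         else shifts$atom == atom
  x <- shifts$ppm[sel & !is.na(shifts$ppm)]
  if (length(x) < 2) rlang::abort("Fewer than 2 matching shifts.")
  if (atom %in% c("H", "HN") && any(x < -2 | x > 13)) {
    rlang::warn("1H shifts outside [-2, 13] ppm; check referencing.")
  }
  max(x) - min(x)
}

#' Classify helix versus coil from carbon secondary shifts
#'
#' A deliberately simple dihedral-free classifier: the secondary shift
#' difference `d(CA) - d(CB)` relative to random-coil values is smoothed
#' with a three-residue window, and runs of at least `min_len` residues at
#' or above `threshold_ppm` (default +1.4 ppm) are called helix; everything
#' else is coil. Residues lacking a CA or CB shift (or a random-coil entry)
#' are skipped.
#'
#' @param shifts Data frame with columns `residue`, `resname` (3-letter),
#'   `atom` (`"CA"`/`"CB"`), `ppm`.
#' @param random_coil Reference table as from [random_coil_shifts()].
#' @param threshold_ppm Helix threshold on the smoothed secondary shift.
#' @param min_len Minimum helix run length.
#' @return Tibble with columns `residue`, `resname`, `secondary_shift`
#'   (smoothed, ppm) and `state` (`"helix"`/`"coil"`).
#' @export
classify_secondary_shifts <- function(shifts, random_coil = random_coil_shifts(),
                                      threshold_ppm = 1.4, min_len = 4) {
  shifts <- tibble::as_tibble(shifts)
  need <- c("residue", "resname", "atom", "ppm")
  if (!all(need %in% names(shifts))) {
    rlang::abort("`shifts` needs columns residue, resname, atom, ppm.")
  }
  wide <- shifts |>
    dplyr::filter(.data$atom %in% c("CA", "CB")) |>
    dplyr::distinct(.data$residue, .data$resname, .data$atom, .keep_all = TRUE) |>
    tidyr::pivot_wider(id_cols = c("residue", "resname"),
                       names_from = "atom", values_from = "ppm") |>
    dplyr::arrange(.data$residue)
  if (!"CB" %in% names(wide)) wide$CB <- NA_real_
  if (!"CA" %in% names(wide)) rlang::abort("No CA shifts present.")
  wide <- dplyr::left_join(wide, random_coil, by = "resname")
  skipped <- is.na(wide$CA) | is.na(wide$ca) |
    (wide$resname != "GLY" & (is.na(wide$CB) | is.na(wide$cb)))
  if (any(skipped)) {
    rlang::warn(sprintf("Skipping %d residue(s) without usable shifts.",
                        sum(skipped)))
    wide <- wide[!skipped, ]
  }
  dca <- wide$CA - wide$ca
  dcb <- ifelse(wide$resname == "GLY", 0, wide$CB - wide$cb)
  sec <- .roll3(dca - dcb)
  runs <- .runs_with_gaps(sec >= threshold_ppm, min_len, bridge_single = FALSE)
  state <- rep("coil", nrow(wide))
  for (i in seq_len(nrow(runs))) state[runs$start[i]:runs$end[i]] <- "helix"
  tibble::tibble(residue = wide$residue, resname = wide$resname,
                 secondary_shift = sec, state = state)
}

#' Read assigned chemical shifts from an NMR-STAR 3.1 file
#'
#' A minimal reader for the `Atom_chem_shift` loop of an NMR-STAR 3.1
#' deposition: it locates the loop, reads the tag order, and extracts the
#' residue number, residue type, atom name and shift value from each data
#' row. Quoted values and comment lines are handled; the rest of the file is
#' ignored.
#'
#' @param path Path to an NMR-STAR 3.1 text file.
#' @return Tibble with columns `residue`, `resname`, `atom`, `ppm`.
#' @export
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  for (ls in loop_starts) {
    tags <- character()
    i <- ls + 1
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, sub("^\\s*(\\S+).*$", "\\1", lines[i]))
      i <- i + 1
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    field <- function(nm) match(paste0("_Atom_chem_shift.", nm), tags)
    idx <- c(res = field("Seq_ID"), name = field("Comp_ID"),
             atom = field("Atom_ID"), val = field("Val"))
    if (anyNA(idx)) {
      rlang::abort("Atom_chem_shift loop lacks Seq_ID/Comp_ID/Atom_ID/Val tags.")
    }
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln %in% c("stop_", "") || startsWith(ln, "#")) {
        if (ln == "stop_") break
        i <- i + 1; next
      }
      rows[[length(rows) + 1L]] <- scan(text = ln, what = character(),
                                        quiet = TRUE)
      i <- i + 1
    }
    if (!length(rows)) rlang::abort("Atom_chem_shift loop has no data rows.")
    mat <- do.call(rbind, rows)
    return(tibble::tibble(
      residue = as.integer(mat[, idx["res"]]),
      resname = toupper(mat[, idx["name"]]),
      atom = toupper(mat[, idx["atom"]]),
      ppm = as.numeric(mat[, idx["val"]])
    ))
  }
  rlang::abort("No Atom_chem_shift loop found in file.")
}
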