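# Colorimetric and radical-scavenging assay arithmetic.
#
# Total flavonoid content is read against a rutin standard curve at 510 nm;
# radical scavenging (DPPH 517 nm, ABTS 734 nm, superoxide 560 nm) is the
# fractional drop in absorbance of the radical solution, and IC50 is the
# extract concentration at 50% scavenging.

#' Rutin calibration curve
#'
#' @param slope OD per (mg/mL); must be > 0.
#' @param intercept OD at zero concentration.
#' @param r_squared Coefficient of determination in \[0, 1\].
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, r_squared = NA_real_) {
  if (!is.numeric(slope) || slope <= 0) stop("slope must be > 0",
                                             call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must be in [0, 1]", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared), class = "calibration_curve")
}

#' Fit a standard curve by ordinary least squares
#'
#' Regresses optical density on standard concentration (OD = B x conc + A).
#'
#' @param concentrations Standard concentrations (mg/mL), at least 3 distinct.
#' @param ods Matching optical densities.
#' @return A [calibration_curve()].
#' @export
fit_calibration <- function(concentrations, ods) {
  if (length(concentrations) != length(ods)) {
    stop("concentrations and ods must have equal length", call. = FALSE)
  }
  if (length(concentrations) < 3L || length(unique(concentrations)) < 2L) {
    stop("need at least 3 points with distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(ods ~ concentrations)
  cf <- stats::coef(fit)
  r2 <- summary(fit)$r.squared
  calibration_curve(slope = unname(cf[2]), intercept = unname(cf[1]),
                    r_squared = r2)
}

#' Extraction constants for the total-flavonoid computation
#'
#' @param sample_mass Dry sample mass extracted (g), default 1.
#' @param extract_volume Constant final volume (mL), default 50.
#' @param aliquot_factor Aliquot ratio (default 5, a 2 mL aliquot of a 10 mL
#'   reaction basis).
#' @param dilution_factor Extra dilution applied before reading, default 1.
#' @return Object of class `extraction_spec`.
#' @export
extraction_spec <- function(sample_mass = 1, extract_volume = 50,
                            aliquot_factor = 5, dilution_factor = 1) {
  vals <- c(sample_mass, extract_volume, aliquot_factor, dilution_factor)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all extraction constants must be positive", call. = FALSE)
  }
  structure(list(sample_mass = sample_mass, extract_volume = extract_volume,
                 aliquot_factor = aliquot_factor,
                 dilution_factor = dilution_factor),
            class = "extraction_spec")
}

#' Total flavonoid content from an OD triplicate
#'
#' TFC (%) = ((mean OD - A) / B) x aliquot_factor x (volume / 1000) x
#' dilution_factor x 100, with A and B the calibration intercept and slope;
#' mg/g (rutin equivalents per dry mass) = TFC% x 10. A mean OD below the
#' intercept (blank-level signal) yields 0 with `blank_flag = TRUE` and a
#' warning. A triplicate coefficient of variation above 10% warns.
#'
#' @param od Numeric vector of 3 optical densities at 510 nm (>= 0).
#' @param curve A [calibration_curve()].
#' @param spec An [extraction_spec()].
#' @return List with `tfc_pct`, `tfc_mg_g`, `mean_od`, `blank_flag`.
#' @export
compute_tfc <- function(od, curve, spec = extraction_spec()) {
  stopifnot(inherits(curve, "calibration_curve"),
            inherits(spec, "extraction_spec"))
  od <- as.numeric(od)
  if (length(od) != 3L || any(!is.finite(od)) || any(od < 0)) {
    stop("`od` must be a triplicate of non-negative absorbances",
         call. = FALSE)
  }
  if (mean(od) > 0 && stats::sd(od) / mean(od) > 0.10) {
    warning("triplicate coefficient of variation exceeds 10%", call. = FALSE)
  }
  m <- mean(od)
  blank <- m < curve$intercept
  if (blank) {
    warning("mean OD below calibration intercept; reporting TFC = 0",
            call. = FALSE)
    conc <- 0
  } else {
    conc <- (m - curve$intercept) / curve$slope
  }
  pct <- conc * spec$aliquot_factor * (spec$extract_volume / 1000) *
    spec$dilution_factor * 100
  list(tfc_pct = pct, tfc_mg_g = pct * 10, mean_od = m, blank_flag = blank)
}

#' Radical-scavenging percentage
#'
#' (1 - A_sample / A_control) x 100. Negative values (sample absorbs more
#' than the control) are returned as-is with a warning, not clipped.
#'
#' @param a_sample Sample absorbance.
#' @param a_control Control absorbance (> 0).
#' @return Scavenging percentage (vectorised over `a_sample`).
#' @export
scavenging_pct <- function(a_sample, a_control) {
  if (!is.numeric(a_control) || any(a_control <= 0)) {
    stop("`a_control` must be > 0", call. = FALSE)
  }
  s <- (1 - a_sample / a_control) * 100
  if (any(s < 0)) {
    warning("negative scavenging percentage (sample above control)",
            call. = FALSE)
  }
  s
}

#' Dose-response series for one antioxidant assay
#'
#' @param assay One of `"DPPH"`, `"ABTS"`, `"superoxide"`.
#' @param concentrations Extract concentrations (mg/mL), strictly increasing.
#' @param sample_absorbances Absorbances at the assay wavelength.
#' @param control_absorbance Control (no extract) absorbance (> 0).
#' @return Object of class `dose_response_series`; the assay wavelength
#'   (517 / 734 / 560 nm) is attached for bookkeeping.
#' @export
dose_response_series <- function(assay, concentrations, sample_absorbances,
                                 control_absorbance) {
  assay <- match.arg(assay, c("DPPH", "ABTS", "superoxide"))
  wl <- c(DPPH = 517, ABTS = 734, superoxide = 560)[[assay]]
  if (length(concentrations) != length(sample_absorbances)) {
    stop("concentrations and absorbances must have equal length",
         call. = FALSE)
  }
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop("concentrations must be positive and strictly increasing",
         call. = FALSE)
  }
  if (!is.numeric(control_absorbance) || control_absorbance <= 0) {
    stop("control_absorbance must be > 0", call. = FALSE)
  }
  structure(list(assay = assay, wavelength = wl,
                 concentrations = as.numeric(concentrations),
                 sample_absorbances = as.numeric(sample_absorbances),
                 control_absorbance = control_absorbance),
            class = "dose_response_series")
}

#' IC50 by log-linear interpolation
#'
#' Computes the scavenging percentage at each concentration and linearly
#' interpolates percentage against log10(concentration) across the first
#' pair of consecutive points bracketing 50%. If the series crosses 50%
#' more than once (local non-monotonicity), the first crossing is used with
#' a warning.
#'
#' @param series A [dose_response_series()], or any list with fields
#'   `concentrations`, `sample_absorbances`, `control_absorbance`.
#' @return IC50 in mg/mL.
#' @export
estimate_ic50 <- function(series) {
  conc <- series$concentrations
  s <- scavenging_pct(series$sample_absorbances, series$control_absorbance)
  if (length(conc) < 2L) stop("need at least 2 dose points", call. = FALSE)

  on_grid <- which(s == 50)
  if (length(on_grid) > 0L) return(conc[on_grid[1]])

  cross <- which((s[-length(s)] - 50) * (s[-1] - 50) < 0)
  if (length(cross) == 0L) {
    stop(sprintf(
      "scavenging never crosses 50%% (achieved range %.1f%% to %.1f%%)",
      min(s), max(s)), call. = FALSE)
  }
  if (length(cross) > 1L) {
    warning("multiple 50% crossings; using the first", call. = FALSE)
  }
  i <- cross[1]
  lx <- log10(conc[c(i, i + 1L)])
  frac <- (50 - s[i]) / (s[i + 1L] - s[i])
  10^(lx[1] + frac * (lx[2] - lx[1]))
}

#' Ferric-reducing force readout
#'
#' Corrected absorbance at 700 nm: sample minus reagent blank, floored at 0
#' with a warning when the blank exceeds the sample.
#'
#' @param a700_sample Absorbance of the reacted part at 700 nm (>= 0).
#' @param a700_blank Absorbance of the blank part at 700 nm (>= 0).
#' @return Corrected absorbance (>= 0).
#' @export
reducing_force <- function(a700_sample, a700_blank) {
  if (any(c(a700_sample, a700_blank) < 0)) {
    stop("absorbances must be >= 0", call. = FALSE)
  }
  d <- a700_sample - a700_blank
  if (d < 0) {
    warning("blank exceeds sample absorbance; flooring at 0", call. = FALSE)
    d <- 0
  }
  d
}
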