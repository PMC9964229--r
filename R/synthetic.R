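# Seeded synthetic-data generators.
#
# Every generator is paired with a downstream estimator and recovers its
# ground truth exactly at zero noise, so the whole pipeline is testable
# without the field campaign's raw data. Defaults emulate a subtropical
# August at nine collection sites: monthly mean temperature near 27 C,
# monsoon-scale precipitation, high relative humidity.

.CLIMATE_FACTORS <- c("AT", "MAT", "MIT", "AP", "DP", "OP", "SD", "ARH")

#' Climate factor codes
#'
#' The eight monthly factors driving the network: AT average temperature,
#' MAT maximum temperature, MIT minimum temperature (deg C); AP average
#' daily precipitation, DP daytime precipitation, OP overnight
#' precipitation (mm); SD sunshine duration (h); ARH average relative
#' humidity (%).
#'
#' @return Character vector of the 8 factor codes.
#' @export
climate_factors <- function() .CLIMATE_FACTORS

#' Generate a site-level climate table
#'
#' Draws per-site monthly climate factors for a subtropical August:
#' AT ~ Normal(27, 2) deg C, MAT/MIT are AT plus/minus positive offsets,
#' total monthly precipitation is log-normal (median 180 mm) split into
#' daytime (DP) and overnight (OP) parts by a Beta(4, 4) fraction, AP is the
#' daily average (total / 31), SD ~ Normal(180, 30) h truncated at 0 and
#' ARH ~ Normal(78, 6) % clamped to \[0, 100\]. By construction
#' MIT <= AT <= MAT and DP + OP equals the total monthly precipitation.
#'
#' @param n_sites Number of sites (>= 2; correlation downstream is undefined
#'   for a single site).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return data.frame with `site_id` and one column per factor code.
#' @export
gen_climate <- function(n_sites = 9, seed = 1) {
  if (!is.numeric(n_sites) || n_sites < 2) {
    stop("`n_sites` must be >= 2", call. = FALSE)
  }
  n <- as.integer(n_sites)
  set.seed(as.integer(seed))
  at <- stats::rnorm(n, 27, 2)
  mat <- at + pmax(stats::rnorm(n, 5, 1), 0.5)
  mit <- at - pmax(stats::rnorm(n, 6, 1), 0.5)
  total_precip <- stats::rlnorm(n, log(180), 0.35)
  day_frac <- stats::rbeta(n, 4, 4)
  dp <- total_precip * day_frac
  op <- total_precip * (1 - day_frac)
  ap <- total_precip / 31
  sd_h <- pmax(stats::rnorm(n, 180, 30), 0)
  arh <- pmin(pmax(stats::rnorm(n, 78, 6), 0), 100)
  data.frame(site_id = sprintf("S%02d", seq_len(n)),
             AT = at, MAT = mat, MIT = mit, AP = ap, DP = dp, OP = op,
             SD = sd_h, ARH = arh, stringsAsFactors = FALSE)
}

#' Effect specification for a synthetic climate response
#'
#' Describes how a compound abundance (or assay readout) responds to the
#' z-scored climate factors: a linear term per factor, an optional Gaussian
#' bump per factor (a localized nonlinearity), and additive Gaussian noise.
#'
#' @param linear Named numeric vector of linear coefficients on z-scored
#'   factors (codes must be climate factor codes).
#' @param bumps Optional named list; each element
#'   `list(center =, width =, amplitude =)` adds
#'   `amplitude * exp(-(z - center)^2 / (2 width^2))` for that factor.
#' @param noise_sd Response noise standard deviation (>= 0).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(linear, bumps = list(), noise_sd = 0) {
  if (is.null(names(linear)) || any(!nzchar(names(linear)))) {
    stop("`linear` must be a named coefficient vector", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (length(bumps) > 0L) {
    ok <- vapply(bumps, function(b) {
      all(c("center", "width", "amplitude") %in% names(b)) && b$width > 0
    }, logical(1))
    if (any(!ok)) stop("each bump needs center, width > 0, amplitude",
                       call. = FALSE)
  }
  structure(list(linear = linear, bumps = bumps, noise_sd = noise_sd),
            class = "effect_spec")
}

.zscore_cols <- function(X) {
  apply(X, 2L, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
}

#' Evaluate an effect spec on a climate table (with planted truth)
#'
#' Z-scores the referenced factors across sites, evaluates the spec's
#' linear-plus-bump function, adds Gaussian noise, and attaches the
#' ground-truth sensitivity vector: the normalized mean absolute partial
#' derivative of the noiseless response with respect to each z-scored
#' factor, averaged over sites — the quantity a one-at-a-time perturbation
#' analysis estimates.
#'
#' @param climate Climate table from [gen_climate()].
#' @param spec An [effect_spec()].
#' @param seed Integer seed for the noise draw.
#' @return List with `response` (numeric per site) and `sensitivity`
#'   (named, non-negative, sums to 1 over all climate factors).
#' @export
gen_response <- function(climate, spec, seed = 1) {
  stopifnot(inherits(spec, "effect_spec"))
  codes <- unique(c(names(spec$linear), names(spec$bumps)))
  unknown <- setdiff(codes, intersect(.CLIMATE_FACTORS, names(climate)))
  if (length(unknown) > 0L) {
    stop("unknown climate factor code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(climate[, .CLIMATE_FACTORS, drop = FALSE])
  Z <- .zscore_cols(X)
  n <- nrow(Z)

  f <- numeric(n)
  dfdz <- matrix(0, n, length(.CLIMATE_FACTORS),
                 dimnames = list(NULL, .CLIMATE_FACTORS))
  for (j in names(spec$linear)) {
    b <- spec$linear[[j]]
    f <- f + b * Z[, j]
    dfdz[, j] <- dfdz[, j] + b
  }
  for (j in names(spec$bumps)) {
    bp <- spec$bumps[[j]]
    z <- Z[, j]
    g <- exp(-(z - bp$center)^2 / (2 * bp$width^2))
    f <- f + bp$amplitude * g
    dfdz[, j] <- dfdz[, j] - bp$amplitude * (z - bp$center) / bp$width^2 * g
  }

  sens <- colMeans(abs(dfdz))
  tot <- sum(sens)
  sens <- if (tot > 0) sens / tot else sens

  set.seed(as.integer(seed))
  noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else
    numeric(n)
  list(response = f + noise, sensitivity = sens)
}

#' Generate a dose-response absorbance series
#'
#' Sample absorbances follow
#' `A_control x (1 - logistic(hill x (log c - log IC50)))` plus Gaussian
#' noise, so the noiseless scavenging percentage is exactly 50 at
#' `c = true_ic50`.
#'
#' @param true_ic50 True IC50 (mg/mL, > 0).
#' @param hill Hill slope of the logistic (default 2).
#' @param concentrations Positive, strictly increasing doses (mg/mL).
#' @param control_abs Control absorbance (default 0.70, the working ABTS
#'   absorbance; any positive value).
#' @param noise_sd Absorbance noise standard deviation (default 0).
#' @param assay Assay label, default `"DPPH"`.
#' @param seed Integer seed.
#' @return A [dose_response_series()].
#' @export
gen_dose_response <- function(true_ic50, hill = 2,
                              concentrations = 10^seq(-1, 1, length.out = 9),
                              control_abs = 0.70, noise_sd = 0,
                              assay = "DPPH", seed = 1) {
  if (!is.numeric(true_ic50) || true_ic50 <= 0) {
    stop("`true_ic50` must be > 0", call. = FALSE)
  }
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop("concentrations must be positive and strictly increasing",
         call. = FALSE)
  }
  s <- stats::plogis(hill * (log(concentrations) - log(true_ic50)))
  set.seed(as.integer(seed))
  noise <- if (noise_sd > 0) stats::rnorm(length(s), 0, noise_sd) else 0
  dose_response_series(assay = assay, concentrations = concentrations,
                       sample_absorbances = control_abs * (1 - s) + noise,
                       control_absorbance = control_abs)
}

#' Generate an OD triplicate for a known total flavonoid content
#'
#' Inverts the total-flavonoid formula: the noiseless mean OD is chosen so
#' that [compute_tfc()] on the output returns `true_tfc` exactly.
#'
#' @param true_tfc True TFC (mg/g rutin equivalents, > 0).
#' @param curve A [calibration_curve()]; default the bundled rutin curve
#'   (slope 10.655, intercept -0.0076).
#' @param spec An [extraction_spec()]; note a dilution factor large enough
#'   to keep the implied OD in \[0, 4\] is required at realistic TFC
#'   (dilution 10 covers 100-400 mg/g).
#' @param noise_sd OD noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return Numeric triplicate of ODs.
#' @export
gen_tfc_od <- function(true_tfc,
                       curve = calibration_curve(10.655, -0.0076),
                       spec = extraction_spec(dilution_factor = 10),
                       noise_sd = 0, seed = 1) {
  if (!is.numeric(true_tfc) || true_tfc <= 0) {
    stop("`true_tfc` must be > 0", call. = FALSE)
  }
  pct <- true_tfc / 10
  conc <- pct / (spec$aliquot_factor * (spec$extract_volume / 1000) *
                   spec$dilution_factor * 100)
  od <- curve$intercept + curve$slope * conc
  if (od < 0 || od > 4) {
    stop(sprintf(
      "implied OD %.3f outside [0, 4]; adjust the dilution factor", od),
      call. = FALSE)
  }
  set.seed(as.integer(seed))
  od + (if (noise_sd > 0) stats::rnorm(3L, 0, noise_sd) else numeric(3L))
}

#' Generate a measured peak list with ppm-scale mass noise
#'
#' Measured m/z = theoretical adduct m/z x (1 + eps / 1e6) with
#' eps ~ Normal(0, ppm_noise).
#'
#' @param formulas Character vector of molecular formulas (non-empty).
#' @param adducts Character vector of adduct names recycled against
#'   formulas (default `"[M-H]-"` for every formula).
#' @param ppm_noise Mass-noise standard deviation in ppm (>= 0).
#' @param seed Integer seed.
#' @return data.frame with `formula`, `adduct`, `theoretical_mz`, `mz`.
#' @export
gen_peak_list <- function(formulas, adducts = "[M-H]-", ppm_noise = 0,
                          seed = 1) {
  if (length(formulas) == 0L) stop("`formulas` must be non-empty",
                                   call. = FALSE)
  if (!is.numeric(ppm_noise) || ppm_noise < 0) {
    stop("`ppm_noise` must be >= 0", call. = FALSE)
  }
  grid <- expand.grid(formula = formulas, adduct = adducts,
                      stringsAsFactors = FALSE)
  theo <- mapply(function(f, a) adduct_mz(f, a), grid$formula, grid$adduct)
  set.seed(as.integer(seed))
  eps <- if (ppm_noise > 0) stats::rnorm(length(theo), 0, ppm_noise) else 0
  data.frame(formula = grid$formula, adduct = grid$adduct,
             theoretical_mz = unname(theo),
             mz = unname(theo * (1 + eps / 1e6)),
             stringsAsFactors = FALSE)
}

.rescale_to <- function(x, lo, hi) {
  r <- range(x)
  if (diff(r) == 0) return(rep((lo + hi) / 2, length(x)))
  lo + (x - r[1]) / diff(r) * (hi - lo)
}

#' Default effect specifications for the eight reference compounds
#'
#' One spec per compound, each dominated by a different climate factor
#' (sunshine duration and temperature prominent, mirroring the factors that
#' drive flavonol/flavone accumulation), with mild secondary terms and a
#' Gaussian bump on the dominant factor of compounds 2 and 6.
#'
#' @param noise_sd Shared response noise sd (default 0.05).
#' @return Named list of [effect_spec()] objects.
#' @export
default_compound_specs <- function(noise_sd = 0.05) {
  dom <- c("SD", "MAT", "SD", "MIT", "AT", "SD", "ARH", "AP")
  cmp <- c("isotrifolin", "rutin", "myricetin_deoxyhexoside",
           "quercetin_3_rutinoside", "luteolin_6_C_glucoside", "quercitrin",
           "genestein_G2", "luteolin_caffeoyl_glucoside")
  out <- lapply(seq_along(cmp), function(i) {
    lin <- stats::setNames(c(1.5, 0.3), c(dom[i], if (dom[i] == "OP") "SD"
                                          else "OP"))
    bumps <- if (i %in% c(2L, 6L)) {
      stats::setNames(list(list(center = 0, width = 1, amplitude = 0.5)),
                      dom[i])
    } else list()
    effect_spec(linear = lin, bumps = bumps, noise_sd = noise_sd)
  })
  stats::setNames(out, cmp)
}

#' Simulate a full study with known ground truth
#'
#' Generates every pipeline input in one call: a climate table; compound
#' abundance responses with planted sensitivities (log-normal abundances,
#' geometric mean 10 with the climate signal on the log scale); true TFC per
#' site inside `tfc_range` with matching OD triplicates; true IC50 per assay
#' per site with matching dose-response series; and a noisy measured peak
#' list over the reference-library formulas.
#'
#' @param n_sites Number of sites (default 9).
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param tfc_range True-TFC range in mg/g (default `c(120, 350)`, inside
#'   the 114.5-345.4 mg/g window the assays report for this fern).
#' @param od_noise_sd,abs_noise_sd,ppm_noise Stage noise levels (defaults
#'   0.005 OD, 0.005 absorbance, 2 ppm).
#' @param compound_specs Named list of [effect_spec()]s; default
#'   [default_compound_specs()].
#' @return List of class `synthetic_study` with elements `climate`,
#'   `responses` (site x compound abundances), `truth` (tfc, ic50,
#'   abundances, sensitivities), `od` (per-site triplicates), `dose_response`
#'   (long data.frame), `peaks`, and `seed`.
#' @export
simulate_study <- function(n_sites = 9, seed = 1,
                           tfc_range = c(120, 350),
                           od_noise_sd = 0.005, abs_noise_sd = 0.005,
                           ppm_noise = 2,
                           compound_specs = default_compound_specs()) {
  seed <- as.integer(seed)
  climate <- gen_climate(n_sites, seed = seed)
  n <- nrow(climate)

  resp <- lapply(seq_along(compound_specs), function(i) {
    gen_response(climate, compound_specs[[i]], seed = seed + 100L + i)
  })
  names(resp) <- names(compound_specs)
  abund <- vapply(resp, function(r) 10 * exp(0.3 * r$response), numeric(n))
  rownames(abund) <- climate$site_id
  sens <- vapply(resp, function(r) r$sensitivity,
                 numeric(length(.CLIMATE_FACTORS)))

  # true TFC follows a temperature-dominated latent response
  tfc_lat <- gen_response(
    climate, effect_spec(linear = c(MIT = -1, AP = 0.4, ARH = 0.3),
                         noise_sd = 0.1), seed = seed + 200L)
  true_tfc <- .rescale_to(tfc_lat$response, tfc_range[1], tfc_range[2])
  od <- t(vapply(seq_len(n), function(i) {
    gen_tfc_od(true_tfc[i], noise_sd = od_noise_sd, seed = seed + 300L + i)
  }, numeric(3L)))

  assays <- c("DPPH", "ABTS", "superoxide")
  ic50_lat <- lapply(seq_along(assays), function(k) {
    gen_response(climate,
                 effect_spec(linear = stats::setNames(
                   c(0.8, -0.5), c(c("DP", "MAT", "ARH")[k], "MIT")),
                   noise_sd = 0.1),
                 seed = seed + 400L + k)$response
  })
  true_ic50 <- vapply(ic50_lat, function(l) exp(.rescale_to(l, log(0.3),
                                                            log(3))),
                      numeric(n))
  colnames(true_ic50) <- assays
  rownames(true_ic50) <- climate$site_id

  dr <- do.call(rbind, lapply(seq_along(assays), function(k) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      ser <- gen_dose_response(
        true_ic50[i, k], hill = 2,
        concentrations = 10^seq(-1.5, 1.5, length.out = 11),
        noise_sd = abs_noise_sd, assay = assays[k],
        seed = seed + 500L + k * 100L + i)
      data.frame(assay = assays[k], site_id = climate$site_id[i],
                 concentration = ser$concentrations,
                 absorbance = ser$sample_absorbances,
                 control = ser$control_absorbance,
                 stringsAsFactors = FALSE)
    }))
  }))

  lib <- flavonoid_library()
  peaks <- gen_peak_list(unique(lib$formula), c("[M-H]-", "[M+H]+"),
                         ppm_noise = ppm_noise, seed = seed + 600L)

  structure(list(climate = climate, responses = abund,
                 truth = list(tfc = stats::setNames(true_tfc,
                                                    climate$site_id),
                              ic50 = true_ic50, abundances = abund,
                              sensitivities = sens),
                 od = od, dose_response = dr, peaks = peaks, seed = seed),
            class = "synthetic_study")
}
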