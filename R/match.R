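# Candidate-formula matching and peak annotation.
#
# The matcher re-implements the vendor "automatic match": enumerate CHNOS
# compositions within element bounds, keep those whose theoretical adduct m/z
# lies within a ppm tolerance of the measurement and whose RDBE is plausible,
# and rank by |ppm error|. Enumeration is organised by solving for the
# hydrogen count in each (C, N, O, S) cell, which visits exactly the same
# candidate set as a full five-deep loop over the bounds.

#' Default element-count bounds for formula matching
#'
#' @return Named list of `c(min, max)` integer ranges for C, H, N, O, S.
#' @export
default_bounds <- function() {
  list(C = c(0L, 60L), H = c(0L, 100L), N = c(0L, 5L),
       O = c(0L, 20L), S = c(0L, 2L))
}

.bounds_size <- function(bounds) {
  prod(vapply(bounds, function(b) b[2] - b[1] + 1, numeric(1)))
}

#' Match candidate molecular formulas to a measured m/z
#'
#' Exhaustively searches CHNOS compositions within `bounds` for formulas whose
#' theoretical m/z for `adduct` is within `tol_ppm` of `measured_mz`, filters
#' on ring-and-double-bond equivalents (RDBE in \[0, 40\]), and ranks the
#' survivors by absolute ppm error.
#'
#' @param measured_mz Measured m/z (> 0).
#' @param adduct Adduct name or [adduct_spec()].
#' @param bounds Element-count ranges as in [default_bounds()].
#' @param tol_ppm Tolerance in ppm (> 0), default 5.
#' @return A data.frame with columns `formula`, `C`, `H`, `N`, `O`, `S`,
#'   `neutral_mass`, `theoretical_mz`, `error_ppm`, `error_mda`, `rdbe`,
#'   sorted by `abs(error_ppm)`; zero rows when nothing matches.
#' @examples
#' match_formula(609.1461, "[M-H]-")[1, "formula"]  # "C27H30O16"
#' @export
match_formula <- function(measured_mz, adduct, bounds = default_bounds(),
                          tol_ppm = 5) {
  stopifnot(is.numeric(measured_mz), length(measured_mz) == 1L,
            measured_mz > 0)
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) {
    stop("`tol_ppm` must be > 0", call. = FALSE)
  }
  if (!inherits(adduct, "adduct_spec")) adduct <- adduct_spec(adduct)
  bounds <- utils::modifyList(default_bounds(), bounds)
  if (any(!vapply(bounds, function(b) length(b) == 2 && all(is.finite(b)) &&
                    b[1] >= 0 && b[2] >= b[1], logical(1)))) {
    stop("each bound must be a finite non-negative c(min, max)", call. = FALSE)
  }
  if (.bounds_size(bounds) > 1e7) {
    stop("element bounds span more than 1e7 combinations; narrow them",
         call. = FALSE)
  }

  # neutral-mass window implied by the ppm window on the ion
  target_neutral <- (measured_mz * abs(adduct$charge) -
                       adduct$proton_delta * .PROTON_MASS) / adduct$multimer
  tol_da <- measured_mz * tol_ppm * 1e-6 * abs(adduct$charge) /
    adduct$multimer

  grid <- expand.grid(
    C = seq.int(bounds$C[1], bounds$C[2]),
    N = seq.int(bounds$N[1], bounds$N[2]),
    O = seq.int(bounds$O[1], bounds$O[2]),
    S = seq.int(bounds$S[1], bounds$S[2])
  )
  heavy <- grid$C * .MONOISOTOPIC_MASS[["C"]] +
    grid$N * .MONOISOTOPIC_MASS[["N"]] +
    grid$O * .MONOISOTOPIC_MASS[["O"]] +
    grid$S * .MONOISOTOPIC_MASS[["S"]]
  resid <- target_neutral - heavy

  # candidate hydrogen counts bracketing the residual mass
  h_mass <- .MONOISOTOPIC_MASS[["H"]]
  h0 <- round(resid / h_mass)
  out <- vector("list", 3L)
  for (k in -1:1) {
    h <- h0 + k
    ok <- h >= bounds$H[1] & h <= bounds$H[2] &
      abs(resid - h * h_mass) <= tol_da
    if (!any(ok)) next
    cand <- grid[ok, , drop = FALSE]
    cand$H <- h[ok]
    out[[k + 2L]] <- cand
  }
  cand <- do.call(rbind, out)
  if (is.null(cand) || nrow(cand) == 0L) return(.empty_match())
  cand <- unique(cand)

  neutral <- cand$C * .MONOISOTOPIC_MASS[["C"]] +
    cand$H * .MONOISOTOPIC_MASS[["H"]] +
    cand$N * .MONOISOTOPIC_MASS[["N"]] +
    cand$O * .MONOISOTOPIC_MASS[["O"]] +
    cand$S * .MONOISOTOPIC_MASS[["S"]]
  theo <- (adduct$multimer * neutral + adduct$proton_delta * .PROTON_MASS) /
    abs(adduct$charge)
  ppm <- (measured_mz - theo) / theo * 1e6
  r <- cand$C - cand$H / 2 + cand$N / 2 + 1
  keep <- abs(ppm) <= tol_ppm & r >= 0 & r <= 40 &
    (cand$C + cand$H + cand$N + cand$O + cand$S) >= 1
  if (!any(keep)) return(.empty_match())

  res <- data.frame(
    formula = .format_formula(cand[keep, , drop = FALSE]),
    C = cand$C[keep], H = cand$H[keep], N = cand$N[keep],
    O = cand$O[keep], S = cand$S[keep],
    neutral_mass = neutral[keep],
    theoretical_mz = theo[keep],
    error_ppm = ppm[keep],
    error_mda = (measured_mz - theo[keep]) * 1e3,
    rdbe = r[keep],
    stringsAsFactors = FALSE
  )
  res[order(abs(res$error_ppm)), , drop = FALSE]
}

.empty_match <- function() {
  data.frame(formula = character(), C = integer(), H = integer(),
             N = integer(), O = integer(), S = integer(),
             neutral_mass = numeric(), theoretical_mz = numeric(),
             error_ppm = numeric(), error_mda = numeric(), rdbe = numeric(),
             stringsAsFactors = FALSE)
}

.format_formula <- function(df) {
  apply(df[, c("C", "H", "N", "O", "S"), drop = FALSE], 1L, function(x) {
    paste0(vapply(c("C", "H", "N", "O", "S"), function(el) {
      n <- x[[el]]
      if (n == 0) "" else if (n == 1) el else paste0(el, n)
    }, character(1)), collapse = "")
  })
}

#' Bundled flavonoid reference library
#'
#' Reads the package's reference list of phenolic identities: molecular
#' formula, identity name, compound class (flavonol, flavone, isoflavone,
#' other) and the characteristic UV lambda-max pattern used to disambiguate
#' isomers sharing a formula.
#'
#' @param path Optional path to a CSV with columns `formula`, `identity`,
#'   `class`, `lambda_max` (semicolon-separated nm values); defaults to the
#'   library shipped in `inst/extdata`.
#' @return data.frame with list-column-free layout (`lambda_max` kept as the
#'   semicolon string, parse with [parse_lambda()]).
#' @export
flavonoid_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "flavonoid_library.csv",
                        package = "flaviclim", mustWork = TRUE)
  }
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("formula", "identity", "class", "lambda_max")
  if (!all(need %in% names(lib))) {
    stop("library CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lib
}

#' Parse a semicolon-separated lambda-max pattern
#' @param x Character vector like `"265;285;350"`.
#' @return List of numeric vectors (nm).
#' @export
parse_lambda <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(v) as.numeric(trimws(v)))
}

.lambda_pattern_matches <- function(ref, obs, tol_nm = 5) {
  # every reference band must have an observed band within +/- tol_nm
  if (length(ref) == 0L) return(FALSE)
  if (length(obs) == 0L) return(FALSE)
  all(vapply(ref, function(l) any(abs(obs - l) <= tol_nm), logical(1)))
}

#' Annotate one chromatographic peak
#'
#' Matches a molecular formula to each measured adduct ion, reconciles the
#' matches across adducts, and assigns a tentative identity when the matched
#' formula and UV lambda-max pattern agree with a reference-library entry
#' (each reference band within +/- 5 nm of an observed band). Adducts are
#' consulted in the order \[M-H\]-, \[2M-H\]-, \[M+H\]+, the deprotonated
#' molecule being the most reliably mass-measured species in negative-mode
#' phenolic work; disagreement between adduct-level top candidates raises an
#' ambiguity flag and all candidates are reported.
#'
#' @param peak List/one-row data.frame with fields `peak` (id), `rt_min`,
#'   `adducts` (named numeric vector of measured m/z keyed by adduct name)
#'   and `lambda_max` (numeric vector, nm).
#' @param library Reference table as from [flavonoid_library()].
#' @param bounds,tol_ppm Passed to [match_formula()].
#' @param lambda_tol_nm Band-matching tolerance (nm), default 5.
#' @return Object of class `annotated_peak`: a list with `peak`, `rt_min`,
#'   `formula`, `neutral_mass`, `error_ppm`, `error_mda`, `identity`,
#'   `class`, `lambda_max`, `ambiguous`, `adduct_formulas` (named character
#'   of per-adduct top candidates) and `candidates`.
#' @export
annotate_peak <- function(peak, library = flavonoid_library(),
                          bounds = default_bounds(), tol_ppm = 5,
                          lambda_tol_nm = 5) {
  adducts <- peak$adducts
  if (is.null(adducts) || length(adducts) < 1L) {
    stop("peak must carry at least one measured adduct m/z", call. = FALSE)
  }
  order_pref <- c("[M-H]-", "[2M-H]-", "[M+H]+")
  adducts <- adducts[order(match(names(adducts), order_pref))]

  per_adduct <- lapply(names(adducts), function(a) {
    match_formula(adducts[[a]], a, bounds = bounds, tol_ppm = tol_ppm)
  })
  names(per_adduct) <- names(adducts)
  tops <- vapply(per_adduct, function(m) {
    if (nrow(m) == 0L) NA_character_ else m$formula[1]
  }, character(1))

  hit <- which(!is.na(tops))
  lam <- as.numeric(peak$lambda_max)
  if (length(hit) == 0L) {
    return(structure(list(
      peak = peak$peak, rt_min = peak$rt_min, formula = NA_character_,
      neutral_mass = NA_real_, error_ppm = NA_real_, error_mda = NA_real_,
      identity = NA_character_, class = "unknown", lambda_max = lam,
      ambiguous = FALSE, adduct_formulas = tops, candidates = per_adduct
    ), class = "annotated_peak"))
  }

  primary <- hit[1]
  formula <- unname(tops[primary])
  # conflict = another matched adduct whose candidate set excludes the
  # primary formula entirely (rank disagreement among isobars is routine)
  ambiguous <- any(vapply(hit[-1], function(k) {
    !formula %in% per_adduct[[k]]$formula
  }, logical(1)))
  best <- per_adduct[[primary]][1, ]

  identity <- NA_character_
  klass <- "unknown"
  cand_lib <- library[library$formula == formula, , drop = FALSE]
  if (nrow(cand_lib) > 0L) {
    pats <- parse_lambda(cand_lib$lambda_max)
    ok <- vapply(pats, .lambda_pattern_matches, logical(1), obs = lam,
                 tol_nm = lambda_tol_nm)
    if (any(ok)) {
      # prefer the most specific fully-matched pattern (most reference bands)
      nb <- vapply(pats, length, integer(1))
      nb[!ok] <- -1L
      i <- which.max(nb)
      if (sum(ok & nb == nb[i]) > 1L) {
        warning("multiple library identities match peak ", peak$peak,
                "; reporting the first", call. = FALSE)
      }
      identity <- cand_lib$identity[i]
      klass <- cand_lib$class[i]
    }
  }

  structure(list(
    peak = peak$peak, rt_min = peak$rt_min, formula = formula,
    neutral_mass = best$neutral_mass, error_ppm = best$error_ppm,
    error_mda = best$error_mda, identity = identity, class = klass,
    lambda_max = lam, ambiguous = ambiguous, adduct_formulas = tops,
    candidates = per_adduct
  ), class = "annotated_peak")
}

#' @export
print.annotated_peak <- function(x, ...) {
  cat(sprintf("peak %s (RT %.2f min): %s  %s%s\n",
              as.character(x$peak),
              if (is.null(x$rt_min) || is.na(x$rt_min)) NA_real_ else x$rt_min,
              if (is.na(x$formula)) "<no formula>" else x$formula,
              if (is.na(x$identity)) paste0("class ", x$class)
              else sprintf("%s (%s)", x$identity, x$class),
              if (isTRUE(x$ambiguous)) " [ambiguous]" else ""))
  invisible(x)
}

#' Annotate a peak table
#'
#' Long-format driver over [annotate_peak()]: one input row per measured
#' adduct ion, grouped by peak id.
#'
#' @param peaks data.frame with columns `peak`, `rt_min`, `adduct`, `mz`,
#'   `lambda_max` (semicolon string, repeated within a peak).
#' @param library,bounds,tol_ppm,lambda_tol_nm As in [annotate_peak()].
#' @return data.frame with one row per peak: `peak`, `rt_min`, `formula`,
#'   `neutral_mass`, `error_ppm`, `error_mda`, `lambda_max`, `identity`,
#'   `class`, `ambiguous`.
#' @export
annotate_peaks <- function(peaks, library = flavonoid_library(),
                           bounds = default_bounds(), tol_ppm = 5,
                           lambda_tol_nm = 5) {
  need <- c("peak", "rt_min", "adduct", "mz", "lambda_max")
  if (!all(need %in% names(peaks))) {
    stop("peak table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(peaks$peak)
  rows <- lapply(ids, function(id) {
    sub <- peaks[peaks$peak == id, , drop = FALSE]
    mzs <- stats::setNames(sub$mz, sub$adduct)
    ann <- annotate_peak(
      list(peak = id, rt_min = sub$rt_min[1], adducts = mzs,
           lambda_max = parse_lambda(sub$lambda_max[1])[[1]]),
      library = library, bounds = bounds, tol_ppm = tol_ppm,
      lambda_tol_nm = lambda_tol_nm)
    data.frame(peak = id, rt_min = sub$rt_min[1], formula = ann$formula,
               neutral_mass = ann$neutral_mass, error_ppm = ann$error_ppm,
               error_mda = ann$error_mda,
               lambda_max = sub$lambda_max[1],
               identity = ann$identity, class = ann$class,
               ambiguous = ann$ambiguous, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
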