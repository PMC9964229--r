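# Accurate-mass arithmetic for ESI-TOF flavonoid annotation.
#
# Monoisotopic atomic masses are pinned so that theoretical adduct m/z values
# are reproducible to the 4 decimal places a TOF instrument report prints.

.MONOISOTOPIC_MASS <- c(
  C = 12,               # exact by definition of the unified mass scale
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.PROTON_MASS <- 1.00727646688  # charge carrier, electron-corrected

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula such as `"C27H30O16"` into a named vector of
#' element counts. Supported elements are C, H, N, O and S, which cover the
#' phenolics and flavonoid glycosides this package annotates.
#'
#' @param formula Character scalar, e.g. `"C21H20O12"`. An element symbol
#'   without a following number counts once (`"CH4"` is C1 H4).
#' @return Named integer vector of element counts (only elements present).
#' @examples
#' parse_formula("C27H30O16")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("`formula` must be a single non-empty character string", call. = FALSE)
  }
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  matched <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(attr(tokens, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", matched)
  cnt <- sub("^[A-Za-z]+", "", matched)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  unknown <- setdiff(sym, names(.MONOISOTOPIC_MASS))
  if (length(unknown) > 0L) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(cnt, sym, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[counts > 0L]
  if (length(counts) == 0L || sum(counts) < 1L) {
    stop("formula must contain at least one atom", call. = FALSE)
  }
  counts[order(match(names(counts), names(.MONOISOTOPIC_MASS)))]
}

.as_counts <- function(formula) {
  if (is.character(formula)) return(parse_formula(formula))
  if (is.numeric(formula) && !is.null(names(formula))) {
    unknown <- setdiff(names(formula), names(.MONOISOTOPIC_MASS))
    if (length(unknown) > 0L) {
      stop("unsupported element(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(formula < 0) || any(formula != round(formula))) {
      stop("element counts must be non-negative integers", call. = FALSE)
    }
    if (sum(formula) < 1) stop("formula must contain at least one atom",
                               call. = FALSE)
    return(formula)
  }
  stop("`formula` must be a formula string or named count vector",
       call. = FALSE)
}

#' Monoisotopic (exact) mass of a neutral molecule
#'
#' Sums pinned monoisotopic atomic masses (C = 12 exactly,
#' H = 1.00782503207, N = 14.0030740048, O = 15.9949146196, S = 31.97207100).
#'
#' @param formula Formula string or named element-count vector.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C21H20O12")  # 464.09548
#' @export
monoisotopic_mass <- function(formula) {
  counts <- .as_counts(formula)
  sum(counts * .MONOISOTOPIC_MASS[names(counts)])
}

#' Electrospray adduct specification
#'
#' The three ion species used throughout: the deprotonated molecule
#' `[M-H]-`, the protonated molecule `[M+H]+` and the deprotonated dimer
#' `[2M-H]-`. The name determines multimer count, proton delta and charge.
#'
#' @param name One of `"[M-H]-"`, `"[M+H]+"`, `"[2M-H]-"`.
#' @return An object of class `adduct_spec` with fields `name`, `multimer`,
#'   `proton_delta`, `charge`.
#' @export
adduct_spec <- function(name) {
  name <- as.character(name)
  table <- list(
    "[M-H]-"  = list(multimer = 1L, proton_delta = -1L, charge = -1L),
    "[M+H]+"  = list(multimer = 1L, proton_delta = +1L, charge = +1L),
    "[2M-H]-" = list(multimer = 2L, proton_delta = -1L, charge = -1L)
  )
  if (length(name) != 1L || !name %in% names(table)) {
    stop("unknown adduct: ", name, " (supported: ",
         paste(names(table), collapse = ", "), ")", call. = FALSE)
  }
  structure(c(list(name = name), table[[name]]), class = "adduct_spec")
}

#' Theoretical m/z of an adduct ion
#'
#' m/z = (multimer x neutral mass + proton_delta x 1.00727646688) / |charge|.
#'
#' @param formula Formula string or named element-count vector.
#' @param adduct Adduct name or an [adduct_spec()].
#' @return Theoretical m/z (full precision; round to 4 dp to compare with
#'   instrument reports).
#' @examples
#' adduct_mz("C27H30O16", "[M-H]-")   # 609.1461...
#' adduct_mz("C21H20O12", "[2M-H]-")  # 927.1837...
#' @export
adduct_mz <- function(formula, adduct) {
  if (!inherits(adduct, "adduct_spec")) adduct <- adduct_spec(adduct)
  m <- monoisotopic_mass(formula)
  (adduct$multimer * m + adduct$proton_delta * .PROTON_MASS) /
    abs(adduct$charge)
}

#' m/z of a fragment ion after a neutral loss
#'
#' Neutral-loss arithmetic only: the fragment keeps the parent's charge, so
#' m/z(fragment) = m/z(parent) - mass(loss) / |charge|.
#'
#' @param parent_mz Parent ion m/z.
#' @param loss_formula Formula of the neutral fragment lost.
#' @param charge Absolute charge of the ion (default 1).
#' @return Fragment ion m/z.
#' @export
neutral_loss_mz <- function(parent_mz, loss_formula, charge = 1L) {
  stopifnot(is.numeric(parent_mz), parent_mz > 0)
  parent_mz - monoisotopic_mass(loss_formula) / abs(charge)
}

#' Mass measurement error in ppm and mDa
#'
#' Sign convention: (measured - theoretical), so a measurement above theory
#' is positive in both components.
#'
#' @param measured Measured m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return Object of class `mass_error` with fields `ppm` and `mda`.
#' @export
mass_error <- function(measured, theoretical) {
  if (!is.numeric(theoretical) || any(theoretical <= 0)) {
    stop("`theoretical` must be > 0", call. = FALSE)
  }
  d <- measured - theoretical
  structure(list(ppm = d / theoretical * 1e6, mda = d * 1e3),
            class = "mass_error")
}

#' @export
print.mass_error <- function(x, ...) {
  cat(sprintf("mass error: %+.2f ppm (%+.2f mDa)\n", x$ppm, x$mda))
  invisible(x)
}

#' @export
print.adduct_spec <- function(x, ...) {
  cat(sprintf("adduct %s: %dM %+d H, charge %+d\n",
              x$name, x$multimer, x$proton_delta, x$charge))
  invisible(x)
}

#' Ring-and-double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1. Oxygen and sulfur do not contribute.
#'
#' @param counts Named element-count vector or formula string.
#' @return RDBE (may be half-integer for odd-electron compositions).
#' @export
rdbe <- function(counts) {
  counts <- .as_counts(counts)
  g <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  g("C") - g("H") / 2 + g("N") / 2 + 1
}
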