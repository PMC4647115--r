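# Monoisotopic-mass and adduct arithmetic for negative-mode LC-MS annotation.

# Most-abundant-isotope atomic masses (Da), IUPAC/CODATA values.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  P  = 30.97376200,
  S  = 31.97207117,
  Na = 22.98976928
)

.ELECTRON_MASS <- 0.000548579909

#' Parse an elemental formula string
#'
#' Parses a Hill-style formula such as `"C34H67NO3"` into a named count
#' vector. Recognised elements are C, H, N, O, P, S and Na; counts default
#' to 1 when omitted.
#'
#' @param x formula string, or an already-parsed named numeric vector.
#' @return Named numeric vector of element counts, class `elemental_formula`.
#' @examples
#' parse_formula("C9H18O3")
#' @export
parse_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else {
    if (!is.character(x) || length(x) != 1L || !nzchar(x))
      stop("formula must be a single non-empty string")
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    tokens <- regmatches(x, list(m))[[1]]
    if (sum(nchar(tokens)) != nchar(x))
      stop("malformed formula: ", x)
    els <- sub("[0-9]*$", "", tokens)
    cnt <- as.numeric(ifelse(grepl("[0-9]+$", tokens),
                             sub("^[A-Za-z]+", "", tokens), "1"))
    counts <- tapply(cnt, els, sum)
    counts <- setNames(as.numeric(counts), names(counts))
  }
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("element counts must be non-negative")
  if (all(counts == 0)) stop("formula must contain at least one atom")
  structure(counts, class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.elemental_formula <- function(x, ...) {
  x <- x[x > 0]
  ord <- c(intersect(c("C", "H"), names(x)),
           sort(setdiff(names(x), c("C", "H"))))
  paste0(ord, ifelse(x[ord] == 1, "", x[ord]), collapse = "")
}

.formula_combine <- function(a, b, sign = 1) {
  els <- union(names(a), names(b))
  out <- setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + as.numeric(a)
  out[names(b)] <- out[names(b)] + sign * as.numeric(b)
  out
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of the most-abundant-isotope atomic masses of the formula's atoms.
#'
#' @param formula formula string or parsed [parse_formula()] object.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C34H67NO3") # 537.5121
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  sum(.ATOMIC_MASS[names(f)] * as.numeric(f))
}

#' Ion species specification
#'
#' Describes the charged form observed in the mass spectrometer as atoms
#' gained, atoms lost, charge magnitude and polarity. Named presets cover
#' the negative-mode species used in serum profiling:
#' \describe{
#'   \item{`"[M-H]-"`}{deprotonation}
#'   \item{`"[M+Na-2H]-"`}{sodium adduct of the doubly deprotonated species}
#'   \item{`"[M-2H]2-"` (also written `"[M-H]2-"`)}{doubly deprotonated,
#'     z = 2}
#'   \item{`"[M-CHO-H]-"`}{in-source loss; note this label is encoded as the
#'     loss of CH2O plus a proton (total CH3O), which is the arithmetic that
#'     reproduces reference m/z values printed under this label — the literal
#'     reading M - CHO - H does not}
#' }
#'
#' @param ion preset name (one of the above) or `NULL` to build a custom
#'   species from `gains`/`losses`.
#' @param gains,losses formula strings of atoms gained/lost (may be `NULL`).
#' @param z charge magnitude (>= 1).
#' @param polarity `"-"` or `"+"`.
#' @param electron_correction if `TRUE`, the electron mass is added
#'   (negative mode) or subtracted (positive mode) per charge. Off by
#'   default: the H-atom convention, under which `[M-H]-` m/z is simply
#'   M minus one hydrogen atom mass.
#' @return An `ion_spec` object.
#' @export
ion_spec <- function(ion = NULL, gains = NULL, losses = NULL, z = 1,
                     polarity = "-", electron_correction = FALSE) {
  if (!is.null(ion)) {
    spec <- switch(ion,
      "[M-H]-"      = list(gains = NULL, losses = "H", z = 1),
      "[M+Na-2H]-"  = list(gains = "Na", losses = "H2", z = 1),
      "[M-2H]2-"    = ,
      "[M-H]2-"     = list(gains = NULL, losses = "H2", z = 2),
      "[M-CHO-H]-"  = list(gains = NULL, losses = "CH3O", z = 1),
      stop("unknown ion preset: ", ion)
    )
    gains <- spec$gains; losses <- spec$losses; z <- spec$z
    polarity <- "-"
  }
  if (z < 1) stop("charge magnitude z must be >= 1")
  if (!polarity %in% c("-", "+")) stop("polarity must be '-' or '+'")
  structure(list(
    label = if (is.null(ion)) NA_character_ else ion,
    gains = if (is.null(gains)) NULL else parse_formula(gains),
    losses = if (is.null(losses)) NULL else parse_formula(losses),
    z = as.integer(z), polarity = polarity,
    electron_correction = isTRUE(electron_correction)
  ), class = "ion_spec")
}

#' @export
print.ion_spec <- function(x, ...) {
  cat("Ion species:", if (is.na(x$label)) "(custom)" else x$label,
      sprintf("(z=%d, polarity %s%s)\n", x$z, x$polarity,
              if (x$electron_correction) ", electron-corrected" else ""))
  invisible(x)
}

#' Theoretical m/z of an ion species
#'
#' `m/z = (M + mass(gains) - mass(losses) +/- z * m_e) / z`, where the
#' electron term enters only when `electron_correction` is enabled on the
#' ion spec (added for negative polarity, subtracted for positive).
#'
#' @param formula neutral elemental formula (string or parsed).
#' @param ion an [ion_spec()] or preset name string.
#' @return Theoretical m/z.
#' @examples
#' ion_mz("C34H67NO3", "[M-H]-")     # 536.5043
#' ion_mz("C9H18O3", "[M+Na-2H]-")   # 195.0997
#' @export
ion_mz <- function(formula, ion) {
  f <- parse_formula(formula)
  if (is.character(ion)) ion <- ion_spec(ion)
  stopifnot(inherits(ion, "ion_spec"))
  avail <- as.numeric(f)
  names(avail) <- names(f)
  if (!is.null(ion$gains)) avail <- .formula_combine(avail, ion$gains, 1)
  if (!is.null(ion$losses)) {
    after <- .formula_combine(avail, ion$losses, -1)
    if (any(after < 0))
      stop("ion loss exceeds available atoms for element(s): ",
           paste(names(after)[after < 0], collapse = ", "))
  }
  m <- monoisotopic_mass(f)
  if (!is.null(ion$gains))  m <- m + monoisotopic_mass(ion$gains)
  if (!is.null(ion$losses)) m <- m - monoisotopic_mass(ion$losses)
  if (ion$electron_correction)
    m <- m + (if (ion$polarity == "-") 1 else -1) * ion$z * .ELECTRON_MASS
  m / ion$z
}

#' Mass error in parts per million
#'
#' `ppm = (observed - theoretical) / theoretical * 1e6`.
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return Signed ppm error (unrounded).
#' @examples
#' ppm_error(329.1733, 329.1753) # about -6.1
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Elemental-composition candidate search
#'
#' Exhaustively enumerates formulas within per-element count bounds whose
#' monoisotopic mass lies within a tolerance of a target mass, sorted by
#' absolute error. Optional heuristic filters: the nitrogen rule (an
#' even-electron neutral molecule with an odd nitrogen count has an odd
#' nominal mass) and a non-negative ring-double-bond-equivalent constraint
#' RDBE = C - (H + Na)/2 + N/2 + 1 >= 0.
#'
#' @param target_mass neutral monoisotopic target mass (Da).
#' @param tolerance_mda tolerance in mDa (> 0); the reference workflow used
#'   10 mDa.
#' @param bounds named vector of maximum element counts, e.g.
#'   `c(C = 30, H = 60, O = 10)`. Only listed elements are enumerated.
#' @param nitrogen_rule,rdbe_filter logical flags for the heuristic filters.
#' @return `data.frame` with columns `formula`, `mass`, `error_mda`,
#'   ordered by `abs(error_mda)`.
#' @export
formula_candidates <- function(target_mass, tolerance_mda = 10, bounds,
                               nitrogen_rule = FALSE, rdbe_filter = FALSE) {
  if (tolerance_mda <= 0) stop("tolerance must be positive")
  if (length(bounds) == 0)
    return(data.frame(formula = character(), mass = numeric(),
                      error_mda = numeric()))
  unknown <- setdiff(names(bounds), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s) in bounds: ",
         paste(unknown, collapse = ", "))
  n_comb <- prod(bounds + 1)
  if (n_comb > 1e7)
    stop("bounds produce ", format(n_comb, big.mark = ","),
         " combinations (> 1e7); tighten the per-element maxima or split ",
         "the search by element")
  grids <- lapply(bounds, function(b) 0:b)
  grid <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- names(bounds)
  mass <- drop(grid %*% .ATOMIC_MASS[colnames(grid)])
  err <- (mass - target_mass) * 1000
  keep <- abs(err) <= tolerance_mda & rowSums(grid) > 0
  if (nitrogen_rule && any(keep)) {
    nominal <- round(mass[keep])
    n_n <- if ("N" %in% colnames(grid)) grid[keep, "N"] else 0
    keep[keep] <- (n_n %% 2) == (nominal %% 2)
  }
  if (rdbe_filter && any(keep)) {
    g <- grid[keep, , drop = FALSE]
    cnt <- function(el) if (el %in% colnames(g)) g[, el] else 0
    rdbe <- cnt("C") - (cnt("H") + cnt("Na")) / 2 + cnt("N") / 2 + 1
    keep[keep] <- rdbe >= 0
  }
  if (!any(keep))
    return(data.frame(formula = character(), mass = numeric(),
                      error_mda = numeric()))
  g <- grid[keep, , drop = FALSE]
  fo <- apply(g, 1L, function(row) {
    format.elemental_formula(structure(row[row > 0],
                                       class = "elemental_formula"))
  })
  out <- data.frame(formula = fo, mass = mass[keep], error_mda = err[keep],
                    stringsAsFactors = FALSE)
  out[order(abs(out$error_mda)), , drop = FALSE]
}

#' Positive predictive value of a screening test
#'
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))` — the
#' probability of disease given a positive result, which for a rare disease
#' is dominated by specificity.
#'
#' @param prevalence,sensitivity,specificity proportions in (0, 1].
#' @return PPV as a proportion in (0, 1].
#' @examples
#' screening_ppv(0.001, 0.75, 0.996) # about 0.158
#' @export
screening_ppv <- function(prevalence, sensitivity, specificity) {
  args <- c(prevalence = prevalence, sensitivity = sensitivity,
            specificity = specificity)
  if (any(args <= 0) || any(args > 1))
    stop("all arguments must lie in (0, 1]")
  tp <- sensitivity * prevalence
  fp <- (1 - specificity) * (1 - prevalence)
  if (tp + fp == 0) return(1)
  tp / (tp + fp)
}

#' Batch mass annotation
#'
#' Computes theoretical m/z and mass errors for a table of observed ions.
#'
#' @param x `data.frame` with columns `observed_mz`, `formula` (neutral
#'   elemental formula string) and `ion` (preset name); an optional
#'   `feature_id` column is carried through.
#' @param electron_correction passed to [ion_spec()].
#' @param mz_digits decimals the theoretical m/z is reported (and the
#'   errors computed) at; annotation tables conventionally print m/z to 4
#'   decimals and derive mass errors from the printed values. `NULL`
#'   disables rounding.
#' @return The input with `theoretical_mz`, `error_ppm` and `error_mda`
#'   columns appended.
#' @export
annotate_masses <- function(x, electron_correction = FALSE, mz_digits = 4) {
  stopifnot(is.data.frame(x),
            all(c("observed_mz", "formula", "ion") %in% names(x)))
  theo <- mapply(function(f, i) {
    spec <- ion_spec(i)
    spec$electron_correction <- electron_correction
    ion_mz(f, spec)
  }, x$formula, x$ion)
  x$theoretical_mz <- as.numeric(theo)
  if (!is.null(mz_digits))
    x$theoretical_mz <- round(x$theoretical_mz, mz_digits)
  x$error_ppm <- ppm_error(x$observed_mz, x$theoretical_mz)
  x$error_mda <- (x$observed_mz - x$theoretical_mz) * 1000
  x
}
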