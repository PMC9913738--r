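# Monoisotopic atomic masses (Da), standard reference table. Embedded as
# constants so that m/z arithmetic is bit-stable and needs no runtime lookup.
.ATOMIC_MASS <- c(
  C  = 12.0000000,
  H  = 1.0078250319,
  N  = 14.0030740,
  O  = 15.9949146,
  P  = 30.9737615,
  S  = 31.9720707,
  Na = 22.9897693,
  Cl = 34.9688527
)

# Electron rest mass (Da); subtracted/added per elementary charge so that
# ion m/z refers to the actual ion mass, not the neutral.
.ELECTRON_MASS <- 0.0005486

.ELEMENTS <- names(.ATOMIC_MASS)

# Heavy-isotope model used throughout: 13C always, 37Cl when chlorine is
# present. Mass differences are exact isotope mass differences.
.ISO_13C_ABUNDANCE  <- 0.0107    # atom fraction of 13C (12C = 0.9893)
.ISO_13C_DELTA      <- 1.0033548378
.ISO_37CL_ABUNDANCE <- 0.24229   # atom fraction of 37Cl (35Cl = 0.75771)
.ISO_37CL_DELTA     <- 1.9970499

#' Create an elemental composition
#'
#' An elemental composition is a named integer vector over the supported
#' element set (C, H, N, O, P, S, Na, Cl) with non-negative counts. It is the
#' unit of chemical bookkeeping for the whole package: lipid species,
#' adduct deltas and isotope envelopes are all expressed through it.
#'
#' @param ... element counts by name, e.g. `elemental_composition(C = 42, H = 80,
#'   N = 1, O = 8, P = 1)`.
#' @return an object of class `elemental_composition`: a full-length named
#'   integer vector over the supported elements.
#' @examples
#' pc342 <- elemental_composition(C = 42, H = 80, N = 1, O = 8, P = 1)
#' monoisotopic_mass(pc342)
#' @export
elemental_composition <- function(...) {
  x <- c(...)
  if (length(x) == 0L) x <- integer(0)
  if (is.null(names(x)) && length(x) > 0L)
    stop("element counts must be named")
  bad <- setdiff(names(x), .ELEMENTS)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (any(x < 0)) stop("element counts must be non-negative")
  if (any(x != round(x))) stop("element counts must be integers")
  out <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  out[names(x)] <- as.integer(round(x))
  structure(out, class = "elemental_composition")
}

.as_comp <- function(x) {
  if (inherits(x, "elemental_composition")) return(x)
  do.call(elemental_composition, as.list(x))
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' Element-wise composition arithmetic
#'
#' Addition and subtraction of compositions act element-wise; subtraction
#' that would produce a negative count is a chemistry error and aborts.
#'
#' @param e1,e2 `elemental_composition` objects.
#' @export
Ops.elemental_composition <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "=="))
    stop("operation '", .Generic, "' not defined for compositions")
  if (.Generic == "==") return(all(unclass(e1) == unclass(e2)))
  v <- get(.Generic)(unclass(e1), unclass(e2))
  if (any(v < 0))
    stop("composition subtraction yields negative count for: ",
         paste(names(v)[v < 0], collapse = ", "))
  structure(as.integer(v), names = names(v), class = "elemental_composition")
}

#' Monoisotopic mass of a composition
#'
#' Sum of embedded monoisotopic atomic masses; chlorine counts as 35Cl
#' (the lightest, most abundant isotope), per the definition of
#' "monoisotopic".
#'
#' @param comp an `elemental_composition`.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  comp <- .as_comp(comp)
  if (sum(comp) == 0L) stop("empty composition")
  sum(.ATOMIC_MASS * unclass(comp))
}

#' Format a composition as a molecular formula string
#'
#' Hill-like ordering (C, H, then remaining elements alphabetically);
#' elements with zero count are omitted, unit counts print without a digit.
#'
#' @param comp an `elemental_composition`.
#' @export
format_formula <- function(comp) {
  comp <- .as_comp(comp)
  v <- unclass(comp)
  ord <- c("C", "H", sort(setdiff(.ELEMENTS, c("C", "H"))))
  v <- v[ord]
  v <- v[v > 0]
  if (!length(v)) return("")
  paste0(names(v), ifelse(v == 1L, "", v), collapse = "")
}

#' Parse a molecular formula string into a composition
#'
#' Inverse of [format_formula()]; accepts e.g. `"C42H80NO8P"`.
#'
#' @param formula a molecular formula string.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(n == "", 1L, as.integer(n))
  counts <- tapply(n, el, sum)
  do.call(elemental_composition, as.list(counts))
}
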