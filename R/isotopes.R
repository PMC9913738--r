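# Fine isotope envelopes --------------------------------------------------

#' Fine isotope envelope of a composition
#'
#' Isotopologue peaks from natural heavy-isotope incorporation, relative to
#' the monoisotopic peak (A0 = 1). The model carries 13C (always, the
#' dominant contributor for lipids) and 37Cl (whenever the composition
#' contains chlorine, i.e. for chloride adduct ions); abundances follow the
#' binomial law, mass offsets are exact isotope mass differences, so e.g.
#' the two-13C and the one-37Cl isotopologues appear as distinct fine-
#' structure peaks (+2.0067 vs +1.9970 Da).
#'
#' The envelope is truncated at nominal offset `n_peaks - 1`, i.e.
#' `n_peaks = 3` keeps isotopologues up to the A2 cluster.
#'
#' @param composition an `elemental_composition` (ion or neutral).
#' @param n_peaks number of nominal isotope peaks to keep (>= 1).
#' @return data.frame with columns `offset` (Da, relative to monoisotopic
#'   mass), `abundance` (relative to A0 = 1), `n13c`, `n37cl`; sorted by
#'   offset, monoisotopic row first.
#' @examples
#' env <- isotope_distribution(parse_formula("C42H80NO8P"), 3)
#' env$abundance[env$n13c == 1]  # ~0.454 for 42 carbons
#' @export
isotope_distribution <- function(composition, n_peaks = 3L) {
  composition <- .as_comp(composition)
  if (sum(composition) == 0L) stop("empty composition")
  if (n_peaks < 1L) stop("n_peaks must be >= 1")
  nC <- composition[["C"]]
  nCl <- composition[["Cl"]]
  rC <- .ISO_13C_ABUNDANCE / (1 - .ISO_13C_ABUNDANCE)
  rCl <- .ISO_37CL_ABUNDANCE / (1 - .ISO_37CL_ABUNDANCE)
  max13 <- min(nC, n_peaks - 1L)
  max37 <- min(nCl, (n_peaks - 1L) %/% 2L)
  i <- rep.int(0:max13, max37 + 1L)
  j <- rep(0:max37, each = max13 + 1L)
  keep <- i + 2L * j <= n_peaks - 1L
  i <- i[keep]; j <- j[keep]
  out <- data.frame(offset = i * .ISO_13C_DELTA + j * .ISO_37CL_DELTA,
                    abundance = choose(nC, i) * rC^i *
                                choose(nCl, j) * rCl^j,
                    n13c = i, n37cl = j)
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Monoisotopic fraction A0 / sum(envelope) for a species/adduct ion at the
# given truncation. The type-I isotopic correction divides the observed
# monoisotopic intensity by this fraction, converting it to a total-species
# intensity comparable across carbon numbers.
.mono_fraction <- function(species, adduct, registry, n_peaks = 3L) {
  env <- isotope_distribution(.ion_composition(species, adduct, registry),
                              n_peaks)
  env$abundance[env$n13c == 0 & env$n37cl == 0] / sum(env$abundance)
}

# Instrument resolution model ---------------------------------------------

#' Resolving power and peak width at a given m/z
#'
#' Orbitrap-style resolution scaling: `R(m) = R200 * sqrt(200 / m)` from the
#' nominal resolving power `R200` quoted at m/z 200 (default 240,000). The
#' full width at half maximum is then `m / R(m)`. Two centroids closer than
#' one FWHM are treated as unresolved throughout the package: the synthetic
#' generator merges them into a single weighted centroid, and the type-II
#' isotope and sodium-overlap corrections use the same criterion to decide
#' which interferences need subtracting.
#'
#' @param mz m/z value(s).
#' @param resolution_at_200 resolving power at m/z 200.
#' @return FWHM in Da at each `mz`.
#' @export
peak_fwhm <- function(mz, resolution_at_200 = 240000) {
  mz^1.5 / (resolution_at_200 * sqrt(200))
}

# Two Gaussian peaks of comparable height collapse into a single maximum
# when their separation drops below 2 sigma = FWHM / 1.18; centroids closer
# than this fraction of the FWHM are treated as one peak everywhere
# (generator merging and correction bookkeeping use the identical rule).
.MERGE_FRAC <- 0.85
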