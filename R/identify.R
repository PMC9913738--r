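# Peak identification -----------------------------------------------------

#' Build the theoretical candidate ion index for one polarity
#'
#' Enumerates every admissible (species, adduct) ion of the registry whose
#' theoretical m/z falls inside the acquisition mass range, for the given
#' polarity. PC-type classes appear in both polarities (chloride adducts in
#' negative mode, protonated and sodiated ions in positive mode). Internal
#' standards can be appended so they are annotated alongside endogenous
#' species.
#'
#' @param registry a `lipid_registry`.
#' @param polarity `"negative"` or `"positive"`.
#' @param mass_range numeric(2) acquisition window (default m/z 400-1300).
#' @param c_range,db_range optional global overrides of the per-class grids.
#' @param standards optional `standard_set` whose species are added to the
#'   index (flagged in the `is_standard` column).
#' @return a `candidate_index` data.frame sorted by m/z with columns
#'   `mz`, `species`, `class_name`, `adduct`, `charge`, `is_standard`.
#' @export
build_candidates <- function(registry, polarity = c("negative", "positive"),
                             mass_range = c(400, 1300),
                             c_range = NULL, db_range = NULL,
                             standards = NULL) {
  polarity <- match.arg(polarity)
  if (length(registry) == 0L) stop("empty class registry")
  acc <- list(mz = numeric(0), species = character(0),
              class_name = character(0), adduct = character(0),
              charge = integer(0), is_standard = logical(0))
  add_ion <- function(sp, adduct, is_standard) {
    mz <- adduct_mz(sp, adduct, registry)
    if (mz < mass_range[1] || mz > mass_range[2]) return()
    n <- length(acc$mz) + 1L
    acc$mz[n] <<- mz
    acc$species[n] <<- species_label(sp)
    acc$class_name[n] <<- sp$class_name
    acc$adduct[n] <<- adduct
    acc$charge[n] <<- .adduct_def(adduct)$charge
    acc$is_standard[n] <<- is_standard
  }
  for (cls in names(registry)) {
    def <- registry[[cls]]
    adducts <- Filter(function(a) .adduct_polarity(a) == polarity,
                      .class_adducts(def))
    if (!length(adducts)) next
    for (sp in .grid_species(cls, registry, c_range, db_range))
      for (a in adducts) add_ion(sp, a, FALSE)
  }
  if (!is.null(standards)) {
    for (k in seq_len(nrow(standards))) {
      def <- registry[[standards$class_name[k]]]
      adducts <- Filter(function(a) .adduct_polarity(a) == polarity,
                        .class_adducts(def))
      sp <- parse_sum_formula(standards$species[k], registry)
      for (a in adducts) add_ion(sp, a, TRUE)
    }
  }
  out <- as.data.frame(acc)
  out <- unique(out[order(out$mz, out$species), , drop = FALSE])
  rownames(out) <- NULL
  structure(out, polarity = polarity, mass_range = mass_range,
            class = c("candidate_index", "data.frame"))
}

#' Match centroid peaks to candidate ions within a ppm tolerance
#'
#' Each candidate is matched to its nearest peak; the match is kept when the
#' signed mass error is within `tol_ppm` (inclusive, symmetric). When one
#' peak is claimable by more than one candidate within tolerance, the
#' candidate with the smallest absolute ppm error wins the peak (ties broken
#' by lower theoretical m/z) and its row is flagged `ambiguous`; the losing
#' candidates are recorded in the `contested` attribute rather than given
#' rows, so every row carries an actually assigned intensity. Unmatched
#' candidates yield no row (the species is absent from the sample).
#'
#' @param peaks a `peak_list`.
#' @param index a `candidate_index` of the same polarity.
#' @param tol_ppm mass tolerance in ppm (default 2, the platform's setting).
#' @return a `match_table` data.frame with columns `sample_id`, `species`,
#'   `class_name`, `adduct`, `charge`, `is_standard`, `mz_theoretical`,
#'   `mz_observed`, `ppm_error`, `intensity`, `ambiguous`.
#' @export
match_peaks <- function(peaks, index, tol_ppm = 2) {
  stopifnot(inherits(peaks, "peak_list"), inherits(index, "candidate_index"))
  if (!identical(attr(peaks, "polarity"), attr(index, "polarity")))
    stop("peak list and candidate index have different polarities")
  sample_id <- attr(peaks, "sample_id")
  empty <- data.frame(sample_id = character(0), species = character(0),
                      class_name = character(0), adduct = character(0),
                      charge = integer(0), is_standard = logical(0),
                      mz_theoretical = numeric(0), mz_observed = numeric(0),
                      ppm_error = numeric(0), intensity = numeric(0),
                      ambiguous = logical(0))
  if (nrow(peaks) == 0L || nrow(index) == 0L)
    return(structure(empty, contested = empty[0, c("species", "adduct")],
                     polarity = attr(peaks, "polarity"),
                     class = c("match_table", "data.frame")))
  # nearest peak per candidate
  pos <- findInterval(index$mz, peaks$mz)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, nrow(peaks))
  nearest <- ifelse(abs(peaks$mz[lo] - index$mz) <= abs(peaks$mz[hi] - index$mz),
                    lo, hi)
  ppm <- (peaks$mz[nearest] - index$mz) / index$mz * 1e6
  keep <- abs(ppm) <= tol_ppm
  cand <- cbind(index[keep, , drop = FALSE],
                peak = nearest[keep], ppm_error = ppm[keep])
  if (nrow(cand) == 0L)
    return(structure(empty, contested = empty[0, c("species", "adduct")],
                     polarity = attr(peaks, "polarity"),
                     class = c("match_table", "data.frame")))
  # resolve contested peaks: min |ppm| wins, ties to lower theoretical m/z
  o <- order(cand$peak, abs(cand$ppm_error), cand$mz)
  cand <- cand[o, , drop = FALSE]
  first <- !duplicated(cand$peak)
  contested_peaks <- unique(cand$peak[duplicated(cand$peak)])
  winners <- cand[first, , drop = FALSE]
  winners$ambiguous <- winners$peak %in% contested_peaks
  losers <- cand[!first, c("species", "adduct"), drop = FALSE]
  out <- data.frame(sample_id = sample_id,
                    species = winners$species,
                    class_name = winners$class_name,
                    adduct = winners$adduct,
                    charge = winners$charge,
                    is_standard = winners$is_standard,
                    mz_theoretical = winners$mz,
                    mz_observed = peaks$mz[winners$peak],
                    ppm_error = winners$ppm_error,
                    intensity = peaks$intensity[winners$peak],
                    ambiguous = winners$ambiguous)
  out <- out[order(out$mz_theoretical), , drop = FALSE]
  rownames(out) <- NULL
  rownames(losers) <- NULL
  structure(out, contested = losers, polarity = attr(peaks, "polarity"),
            class = c("match_table", "data.frame"))
}

#' @export
print.match_table <- function(x, ...) {
  cat("<match_table> ", nrow(x), " assigned ions",
      if (nrow(x)) sprintf(" (%d ambiguous)", sum(x$ambiguous)) else "",
      "\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
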