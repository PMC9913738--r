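# Internal-standard quantification ----------------------------------------

#' Quantify a sample against its class internal standards
#'
#' For each class, the corrected intensity of every species in the class's
#' quantification adduct is compared with the corrected intensity of the
#' class standard in the same sample and polarity:
#'
#'     pmol(species) = I(species) / I(standard) x pmol(standard)
#'
#' Classes whose standard is unmatched (or has zero intensity) are flagged
#' unquantifiable for the sample and their species are dropped with a
#' warning; other classes are unaffected. Class totals, the membrane total
#' (glycerophospho- + sphingolipids; DG/TG/CE excluded) and mol% of
#' membrane lipids are computed.
#'
#' @param matches a corrected `match_table` (or an rbind of the negative-
#'   and positive-mode tables of one sample, see [combine_matches()]).
#' @param standards a `standard_set`.
#' @param registry a `lipid_registry`.
#' @return a `quant_lipidome`: data.frame with one row per endogenous
#'   species (`species`, `class_name`, `adduct`, `pmol`, `mol_percent`,
#'   `membrane`, `clipped`, `ambiguous`) and attributes `membrane_total_pmol`,
#'   `class_totals` (data.frame), `unquantifiable` (character vector of
#'   classes), `sample_id`.
#' @export
quantify_pmol <- function(matches, standards = default_standards(registry),
                          registry = default_registry()) {
  stopifnot(inherits(matches, "match_table") || is.data.frame(matches))
  icol <- if ("intensity_corrected" %in% names(matches))
    "intensity_corrected" else "intensity"
  sample_id <- if (length(unique(matches$sample_id)) == 1L)
    matches$sample_id[1] else "multi"
  std_int <- stats::setNames(rep(NA_real_, nrow(standards)),
                             standards$class_name)
  for (k in seq_len(nrow(standards))) {
    cls <- standards$class_name[k]
    qa <- registry[[cls]]$quant_adduct
    row <- matches[matches$species == standards$species[k] &
                   matches$adduct == qa, , drop = FALSE]
    if (nrow(row) == 1L && row[[icol]] > 0) std_int[cls] <- row[[icol]]
  }
  # endogenous species in their class's quantification adduct
  qa_of <- vapply(registry, `[[`, "", "quant_adduct")
  rows <- matches[!matches$is_standard &
                  matches$adduct == qa_of[matches$class_name], , drop = FALSE]
  # a class is unquantifiable when its standard is unmatched or not spiked
  unquant <- union(names(std_int)[is.na(std_int)],
                   setdiff(unique(rows$class_name), standards$class_name))
  dropped <- rows$class_name %in% unquant
  if (any(dropped))
    warning("class(es) unquantifiable (standard missing): ",
            paste(intersect(unquant, rows$class_name), collapse = ", "))
  rows <- rows[!dropped, , drop = FALSE]
  std_pmol <- stats::setNames(standards$pmol, standards$class_name)
  pmol <- rows[[icol]] / std_int[rows$class_name] *
    std_pmol[rows$class_name]
  memb <- rows$class_name %in% membrane_classes(registry)
  membrane_total <- sum(pmol[memb])
  mol_percent <- ifelse(memb & membrane_total > 0,
                        100 * pmol / membrane_total, NA_real_)
  out <- data.frame(sample_id = sample_id,
                    species = rows$species,
                    class_name = rows$class_name,
                    adduct = rows$adduct,
                    pmol = as.numeric(pmol),
                    mol_percent = mol_percent,
                    membrane = memb,
                    clipped = if ("clipped" %in% names(rows)) rows$clipped
                              else FALSE,
                    ambiguous = rows$ambiguous)
  out <- out[order(out$class_name, out$species), , drop = FALSE]
  rownames(out) <- NULL
  ct <- stats::aggregate(pmol ~ class_name, out, sum)
  ct$mol_percent <- ifelse(ct$class_name %in% membrane_classes(registry) &
                             membrane_total > 0,
                           100 * ct$pmol / membrane_total, NA_real_)
  structure(out, membrane_total_pmol = membrane_total, class_totals = ct,
            unquantifiable = unquant, sample_id = sample_id,
            class = c("quant_lipidome", "data.frame"))
}

#' @export
print.quant_lipidome <- function(x, ...) {
  cat("<quant_lipidome> ", attr(x, "sample_id"), ": ", nrow(x),
      " species, membrane total ",
      format(attr(x, "membrane_total_pmol"), digits = 4), " pmol\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8))
  invisible(x)
}

#' Combine negative- and positive-mode match tables of one sample
#'
#' @param neg,pos `match_table`s of the same sample.
#' @return a `match_table` with the union of rows.
#' @export
combine_matches <- function(neg, pos) {
  a <- as.data.frame(neg); b <- as.data.frame(pos)
  for (col in setdiff(names(b), names(a)))
    a[[col]] <- if (is.logical(b[[col]])) FALSE else NA
  for (col in setdiff(names(a), names(b)))
    b[[col]] <- if (is.logical(a[[col]])) FALSE else NA
  out <- rbind(a, b[names(a)])
  structure(out, contested = rbind(attr(neg, "contested"),
                                   attr(pos, "contested")),
            class = c("match_table", "data.frame"))
}

#' Add per-weight normalizations to a quantified lipidome
#'
#' Attaches the spot geometry and derives the membrane lipid density in
#' nmol per mg wet weight (numerically pmol/ug). Requires a positive
#' membrane total.
#'
#' @param q a `quant_lipidome`.
#' @param spot the `spot_spec` the sample came from.
#' @return `q` with added attributes `spot`, `wet_weight_ug`,
#'   `membrane_nmol_per_mg` and a per-species `nmol_per_mg` column.
#' @export
normalize_outputs <- function(q, spot) {
  stopifnot(inherits(q, "quant_lipidome"), inherits(spot, "spot_spec"))
  if (attr(q, "membrane_total_pmol") <= 0)
    stop("membrane total is zero; nothing to normalize")
  ww <- spot_wet_weight(spot)
  q$nmol_per_mg <- q$pmol / ww / 1000 * 1000   # pmol/ug == nmol/mg
  attr(q, "spot") <- spot
  attr(q, "wet_weight_ug") <- ww
  attr(q, "membrane_nmol_per_mg") <- attr(q, "membrane_total_pmol") / ww
  q
}

#' Run identification, correction and quantification on one spot
#'
#' The single-sample pipeline: build candidate indexes for both polarities
#' (with standards), match peaks at the ppm tolerance, apply type-I/II
#' isotopic correction, estimate the sodiation fraction from the chloride
#' profile and (optionally) subtract the sodiated-PC overlap, quantify
#' against the internal standards and normalize to the spot geometry.
#'
#' @param negative,positive `peak_list`s of the spot.
#' @param spot the `spot_spec` (omit to skip weight normalization).
#' @param standards a `standard_set`.
#' @param registry a `lipid_registry`.
#' @param tol_ppm mass tolerance (ppm).
#' @param na_correction apply [na_overlap_correct()] (default TRUE).
#' @param type2 apply type-II isotopic subtraction (default TRUE).
#' @param resolution_at_200,n_iso instrument model, see [isotope_correct()].
#' @param mass_range acquisition window for the candidate indexes.
#' @param candidates optional precomputed list with elements `negative` and
#'   `positive` (from [build_candidates()]); building the indexes once and
#'   reusing them across the spots of a dataset saves most of the runtime.
#' @return a `quant_lipidome` with extra attributes `f_na` (estimated
#'   sodiation fraction) and `matches` (the corrected combined table).
#' @export
quantify_spot <- function(negative, positive, spot = NULL,
                          standards = default_standards(registry),
                          registry = default_registry(), tol_ppm = 2,
                          na_correction = TRUE, type2 = TRUE,
                          resolution_at_200 = 240000, n_iso = 3L,
                          mass_range = c(400, 1300), candidates = NULL) {
  idx_neg <- if (!is.null(candidates)) candidates$negative
    else build_candidates(registry, "negative", mass_range,
                          standards = standards)
  idx_pos <- if (!is.null(candidates)) candidates$positive
    else build_candidates(registry, "positive", mass_range,
                          standards = standards)
  m_neg <- match_peaks(negative, idx_neg, tol_ppm)
  m_pos <- match_peaks(positive, idx_pos, tol_ppm)
  m_neg <- isotope_correct(m_neg, registry, type2, resolution_at_200, n_iso)
  m_pos <- isotope_correct(m_pos, registry, type2, resolution_at_200, n_iso)
  f_na <- NA_real_
  if (na_correction) {
    f_na <- estimate_sodiation(m_pos, m_neg)
    m_pos <- na_overlap_correct(m_pos, f_na, registry,
                                resolution_at_200 = resolution_at_200,
                                n_iso = n_iso)
  }
  q <- quantify_pmol(combine_matches(m_neg, m_pos), standards, registry)
  if (!is.null(spot)) q <- normalize_outputs(q, spot)
  attr(q, "f_na") <- as.numeric(f_na)
  attr(q, "matches") <- combine_matches(m_neg, m_pos)
  q
}

#' Quantify every spot of a simulated or loaded dataset
#'
#' Builds the candidate indexes once and runs [quantify_spot()] over all
#' samples of a dataset (as returned by [simulate_area_series()] or
#' [simulate_regions()]).
#'
#' @param dataset named list of per-spot results (elements `negative`,
#'   `positive`, `spot`) with a `manifest` attribute.
#' @param ... passed on to [quantify_spot()].
#' @inheritParams quantify_spot
#' @return named list of `quant_lipidome`s, manifest attribute carried over.
#' @export
quantify_dataset <- function(dataset, standards = default_standards(registry),
                             registry = default_registry(),
                             mass_range = c(400, 1300), candidates = NULL,
                             ...) {
  cand <- if (!is.null(candidates)) candidates else list(
    negative = build_candidates(registry, "negative", mass_range,
                                standards = standards),
    positive = build_candidates(registry, "positive", mass_range,
                                standards = standards))
  out <- lapply(dataset, function(s)
    quantify_spot(s$negative, s$positive, s$spot, standards, registry,
                  mass_range = mass_range, candidates = cand, ...))
  attr(out, "manifest") <- attr(dataset, "manifest")
  out
}
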