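# Isotopic and adduct-overlap corrections ---------------------------------

#' Type-I and type-II isotopic correction
#'
#' Type I: every matched monoisotopic intensity is divided by the
#' monoisotopic fraction A0/sum(A) of its ion's truncated isotope envelope,
#' converting it to a total-species intensity and making species of
#' different carbon number comparable.
#'
#' Type II (default on): an isotopologue peak of a lighter annotated ion
#' can be unresolvable from the monoisotopic peak of a heavier one, in
#' which case the observed centroid carries both. The canonical case is
#' the same-class double-bond ladder — the two-13C cluster of the C:DB+1
#' homolog sits only ~0.009/|z| Da below the monoisotopic peak of C:DB,
#' unresolved for doubly charged cardiolipins throughout the mass range
#' and for singly charged lipids towards the top of it — but cross-class
#' coincidences (e.g. an A+1 peak of a sphingomyelin next to an ammoniated
#' triacylglycerol) are handled by the same rule. The correction
#' reconstructs which predicted envelope peaks of all annotated ions are
#' unresolved from which monoisotopic positions, using the identical
#' clustering criterion as the resolution model, and subtracts the
#' predicted leak in ascending m/z order so every contaminator has already
#' been corrected when its contribution is predicted.
#'
#' @param matches a `match_table`.
#' @param registry a `lipid_registry`.
#' @param type2 apply the type-II subtraction (default TRUE).
#' @param resolution_at_200 resolving power at m/z 200 for the overlap
#'   criterion (default 240,000).
#' @param n_iso envelope truncation; must equal the truncation used when
#'   the intensities were produced for exact recovery (default 3).
#' @return the `match_table` with added columns `intensity_corrected`
#'   (total-species scale) and `clipped` (TRUE where a subtraction was
#'   clipped at zero).
#' @export
isotope_correct <- function(matches, registry = default_registry(),
                            type2 = TRUE, resolution_at_200 = 240000,
                            n_iso = 3L) {
  stopifnot(inherits(matches, "match_table"))
  out <- matches
  n <- nrow(out)
  out$intensity_corrected <- numeric(n)
  out$clipped <- logical(n)
  if (n == 0L) return(out)
  fp <- .registry_fingerprint(registry)
  ions <- lapply(seq_len(n), function(i)
    .ion_info(out$species[i], out$adduct[i], registry, n_iso, fp))
  envs <- lapply(ions, `[[`, "env")
  mono_frac <- vapply(ions, `[[`, 0, "mono_frac")
  # Predicted positions of every envelope peak of every annotated ion,
  # clustered with the resolution model's merge rule: peaks in the cluster
  # of a monoisotopic position are unresolved from it.
  peaks <- do.call(rbind, lapply(seq_len(n), function(i) {
    e <- envs[[i]]
    data.frame(row = i,
               pos = out$mz_theoretical[i] + e$offset / abs(out$charge[i]),
               share = e$abundance / sum(e$abundance),
               mono = e$n13c == 0 & e$n37cl == 0)
  }))
  peaks <- peaks[order(peaks$pos), , drop = FALSE]
  gap <- diff(peaks$pos)
  fw <- .MERGE_FRAC * peak_fwhm(peaks$pos[-nrow(peaks)], resolution_at_200)
  peaks$cluster <- cumsum(c(1L, as.integer(gap >= fw)))
  mono_cluster <- integer(n)
  mono_cluster[peaks$row[peaks$mono]] <- peaks$cluster[peaks$mono]
  # ascending monoisotopic m/z: every contaminator is lighter than the
  # ion it leaks into, so its corrected total is already available
  ord <- order(out$mz_theoretical)
  corrected <- numeric(n)
  for (i in ord) {
    raw <- out$intensity[i]
    if (type2) {
      cl <- peaks[peaks$cluster == mono_cluster[i] & peaks$row != i, ,
                  drop = FALSE]
      if (nrow(cl)) {
        # corrected[] is on the total-species scale; share is the
        # isotopologue's fraction of that total
        leak <- sum(corrected[cl$row] * cl$share)
        raw <- raw - leak
        if (raw < 0) { raw <- 0; out$clipped[i] <- TRUE }
      }
    }
    corrected[i] <- raw / mono_frac[i]
  }
  out$intensity_corrected <- corrected
  out
}

#' Estimate the sodiated/protonated PC adduct fraction
#'
#' The sodiated ion of PC(x:y) is isobaric with the protonated ion of
#' PC(x+2:y+3) (0.0024 Da apart, unresolved), so the Na/H intensity ratio
#' can only be read off species whose sodiated position is interference-
#' free. The chloride-adduct profile of PC from the negative-mode spectrum
#' of the same sample supplies the reference relative abundances: a species
#' PC(x:y) is interference-free when its +2C/+3DB partner is absent from
#' (or negligible in) the chloride profile — so its sodiated position is
#' clean — and its -2C/-3DB partner is absent as well — so its own
#' protonated peak carries no foreign sodiated ion. The estimate is the
#' median of
#' I([M+Na]+)/I([M+H]+) over interference-free species, robust to residual
#' interference; a species with no matched sodiated ion contributes a ratio
#' of zero.
#'
#' @param matches_pos positive-mode `match_table` of the sample (after
#'   [isotope_correct()]; raw intensities are used if the corrected column
#'   is absent).
#' @param matches_neg negative-mode `match_table` of the same sample
#'   (supplies the [M+Cl]- reference profile).
#' @param classes PC-type classes the estimator pools (default `"PC"`).
#' @param presence_frac chloride-profile intensity below this fraction of
#'   the species' own chloride intensity counts as absent (default 0.01).
#' @param min_h minimum protonated intensity for a usable species, as a
#'   fraction of the largest protonated PC ion (default 0.01).
#' @param fallback value returned (with a warning) when no interference-
#'   free species is available (default 0.10).
#' @return estimated sodiation fraction in [0, 1], with attribute
#'   `n_species` (number of interference-free species pooled).
#' @export
estimate_sodiation <- function(matches_pos, matches_neg, classes = "PC",
                               presence_frac = 0.01, min_h = 0.01,
                               fallback = 0.10) {
  stopifnot(inherits(matches_pos, "match_table"),
            inherits(matches_neg, "match_table"))
  icol <- if ("intensity_corrected" %in% names(matches_pos))
    "intensity_corrected" else "intensity"
  cl <- matches_neg[matches_neg$class_name %in% classes &
                    matches_neg$adduct == "[M+Cl]-" &
                    !matches_neg$is_standard, , drop = FALSE]
  cl_int <- stats::setNames(cl$intensity, cl$species)
  pos <- matches_pos[matches_pos$class_name %in% classes &
                     !matches_pos$is_standard, , drop = FALSE]
  h <- pos[pos$adduct == "[M+H]+", , drop = FALSE]
  na <- pos[pos$adduct == "[M+Na]+", , drop = FALSE]
  na_int <- stats::setNames(na[[icol]], na$species)
  ratios <- c()
  if (nrow(h)) {
    hmax <- max(h[[icol]])
    for (k in seq_len(nrow(h))) {
      sp <- parse_sum_formula(h$species[k])
      up <- species_label(lipid_species(sp$class_name, sp$carbons + 2L,
                                        sp$double_bonds + 3L))
      down <- if (sp$double_bonds >= 3L && sp$carbons >= 4L)
        species_label(lipid_species(sp$class_name, sp$carbons - 2L,
                                    sp$double_bonds - 3L)) else NA_character_
      own_cl <- cl_int[h$species[k]]
      if (is.na(own_cl)) next                   # no reference profile entry
      hit <- function(p) !is.na(p) && !is.na(cl_int[p]) &&
        cl_int[p] > presence_frac * own_cl
      if (hit(up)) next     # sodiated position carries [up + H]+
      if (hit(down)) next   # own protonated peak carries [down + Na]+
      if (h[[icol]][k] < min_h * hmax) next     # too weak to ratio reliably
      na_i <- na_int[h$species[k]]
      if (is.na(na_i)) na_i <- 0                # sodiated ion below floor
      ratios <- c(ratios, na_i / h[[icol]][k])
    }
  }
  if (!length(ratios)) {
    warning("no interference-free PC species; returning fallback sodiation ",
            "fraction ", fallback)
    return(structure(fallback, n_species = 0L))
  }
  structure(min(max(stats::median(ratios), 0), 1),
            n_species = length(ratios))
}

#' Subtract the sodiated-PC contribution from interfered protonated ions
#'
#' Iterating PC-type species in ascending mass, the predicted sodiated
#' intensity of PC(x:y) — the estimated sodiation fraction times its
#' already-corrected protonated intensity — is removed from the ion matched
#' at the position of [PC(x+2:y+3)+H]+, provided the two positions are
#' unresolved at the instrument's resolving power. The cascade uses
#' corrected upstream values, so chains of interferences unwind from the
#' light end. Non-interfered species are left unchanged; subtraction never
#' drives an intensity below zero (clipped and flagged instead).
#'
#' @param matches a positive-mode `match_table` after [isotope_correct()].
#' @param f_na estimated sodiation fraction (from [estimate_sodiation()]).
#' @param registry a `lipid_registry`.
#' @param classes PC-type classes corrected (default `"PC"`).
#' @param resolution_at_200 resolving power for the unresolved criterion.
#' @param n_iso envelope truncation used for the monoisotopic bookkeeping.
#' @return the `match_table` with `intensity_corrected` overwritten for
#'   interfered species and a logical `na_corrected` column.
#' @export
na_overlap_correct <- function(matches, f_na, registry = default_registry(),
                               classes = "PC", resolution_at_200 = 240000,
                               n_iso = 3L) {
  stopifnot(inherits(matches, "match_table"))
  if (!"intensity_corrected" %in% names(matches))
    stop("run isotope_correct() before na_overlap_correct()")
  out <- matches
  out$na_corrected <- logical(nrow(out))
  idx <- which(out$class_name %in% classes & out$adduct == "[M+H]+")
  if (!length(idx) || f_na <= 0) return(out)
  sub <- out[idx, , drop = FALSE]
  sp_list <- lapply(sub$species, parse_sum_formula, registry = registry)
  labels <- sub$species
  ord <- order(sub$mz_theoretical)
  corrected_h <- stats::setNames(sub$intensity_corrected, labels)
  for (r in ord) {
    sp <- sp_list[[r]]
    if (sp$double_bonds < 3L) next
    light <- species_label(lipid_species(sp$class_name,
                                         sp$carbons - 2L,
                                         sp$double_bonds - 3L))
    if (!light %in% labels) next
    mz_na <- adduct_mz(parse_sum_formula(light, registry), "[M+Na]+",
                       registry, check_admissible = FALSE)
    fw <- .MERGE_FRAC * peak_fwhm(sub$mz_theoretical[r], resolution_at_200)
    if (abs(mz_na - sub$mz_theoretical[r]) >= fw) next
    # predicted monoisotopic contribution of the sodiated light species
    na_total <- f_na * corrected_h[light]
    mono_frac_na <- .mono_fraction(parse_sum_formula(light, registry),
                                   "[M+Na]+", registry, n_iso)
    i <- idx[r]
    mono_frac_h <- .mono_fraction(sp, "[M+H]+", registry, n_iso)
    raw_mono <- out$intensity_corrected[i] * mono_frac_h
    raw_mono <- raw_mono - na_total * mono_frac_na
    if (raw_mono < 0) { raw_mono <- 0; out$clipped[i] <- TRUE }
    out$intensity_corrected[i] <- raw_mono / mono_frac_h
    corrected_h[labels[r]] <- out$intensity_corrected[i]
    out$na_corrected[i] <- TRUE
  }
  out
}
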