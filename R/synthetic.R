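# Synthetic LMD lipidomics data ------------------------------------------
#
# Ground-truth lipidomes, LMD spot geometries and realistic polarity-
# switched centroid peak lists. The generator emulates the acquisition
# design of the platform: spots of 5,000-160,000 um^2 cut from 10 um
# cryosections, class-structured lipidomes with spiked internal standards,
# isotope envelopes, [M-H]-/[M-2H]2-/[M+Cl]-/[M+H]+/[M+Na]+/[M+NH4]+
# adducts, ~ppm-scale mass accuracy, multiplicative intensity noise and an
# optional laser-ablation degradation channel (diacyl -> lyso + PA).

#' LMD spot geometry
#'
#' @param area dissected area in um^2 (> 0); the platform's working range is
#'   5,000-160,000 um^2.
#' @param thickness section thickness in um (default 10, the cryosection
#'   thickness of the workflow).
#' @param region region label (character).
#' @param replicate replicate index.
#' @param density tissue density in ug per um^3; the default 1e-6 equals
#'   1 g/cm^3, which reproduces the printed wet weights of both a 30,000 um^2
#'   spot (0.3 ug) and a 7x7 mm section (490 ug), so it is treated as the
#'   platform's implicit convention.
#' @return a `spot_spec` list.
#' @export
spot_spec <- function(area, thickness = 10, region = "tissue",
                      replicate = 1L, density = 1e-6) {
  if (!is.numeric(area) || area <= 0) stop("area must be > 0")
  if (!is.numeric(thickness) || thickness <= 0) stop("thickness must be > 0")
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  structure(list(area = area, thickness = thickness, region = region,
                 replicate = as.integer(replicate), density = density),
            class = "spot_spec")
}

#' Wet weight of an LMD spot
#'
#' `area x thickness x density`; with the defaults a 30,000 um^2 spot from a
#' 10 um section weighs 0.3 ug.
#'
#' @param spot a `spot_spec`.
#' @return wet weight in ug.
#' @examples
#' spot_wet_weight(spot_spec(30000))          # 0.3 ug
#' spot_wet_weight(spot_spec(49e6))           # 490 ug (7 mm x 7 mm)
#' @export
spot_wet_weight <- function(spot) {
  stopifnot(inherits(spot, "spot_spec"))
  spot$area * spot$thickness * spot$density
}

#' Cell-equivalent count of a dissected volume
#'
#' Dissected volume divided by a typical mammalian cell volume of
#' 4000 um^3: 10,000 um^2 from a 10 um section corresponds to about 25
#' cells, the 5000 um^2 limit of the platform to about ten.
#'
#' @param area dissected area (um^2, > 0).
#' @param thickness section thickness (um, > 0).
#' @param cell_volume cell volume (um^3, default 4000).
#' @return cell count (possibly fractional).
#' @export
cells_equivalent <- function(area, thickness = 10, cell_volume = 4000) {
  if (any(c(area, thickness, cell_volume) <= 0))
    stop("all arguments must be positive")
  area * thickness / cell_volume
}

#' Acquisition / noise model
#'
#' Parameters of the simulated direct-infusion acquisition.
#'
#' @param ppm_sd Gaussian mass error SD in ppm (default 0.5; the platform's
#'   high-resolution analyzer delivers sub-ppm mass accuracy).
#' @param intensity_cv multiplicative log-normal intensity noise CV as a
#'   fraction (default 0.05).
#' @param f_na sodiated/protonated adduct fraction for PC-type classes
#'   (default 0.10, the level at 0.3 mM ammonium chloride).
#' @param cl_fraction chloride-adduct yield in negative mode relative to the
#'   nominal response (default 1; ammonium chloride promotes [M+Cl]-
#'   formation efficiently).
#' @param noise_floor absolute intensity below which peaks are dropped
#'   (default 2e-4 on the pmol-equivalent intensity scale).
#' @param mass_range acquisition window, default m/z 400-1300.
#' @param degradation fraction of each diacyl glycerophospholipid routed to
#'   its lyso partner + PA by laser ablation (default 0).
#' @param resolution_at_200 resolving power at m/z 200 (default 240,000);
#'   controls centroid merging, see [peak_fwhm()].
#' @param n_iso isotope envelope truncation (nominal peaks, default 3).
#' @param seed integer seed making the simulation deterministic.
#' @return an `acquisition_spec` list.
#' @export
acquisition_spec <- function(ppm_sd = 0.5, intensity_cv = 0.05, f_na = 0.10,
                             cl_fraction = 1.0, noise_floor = 2e-4,
                             mass_range = c(400, 1300), degradation = 0,
                             resolution_at_200 = 240000, n_iso = 3L,
                             seed = 1L) {
  stopifnot(ppm_sd >= 0, intensity_cv >= 0,
            f_na >= 0, f_na <= 1, cl_fraction >= 0, cl_fraction <= 1,
            degradation >= 0, degradation <= 1,
            noise_floor >= 0, length(mass_range) == 2,
            mass_range[1] < mass_range[2], n_iso >= 1)
  structure(list(ppm_sd = ppm_sd, intensity_cv = intensity_cv, f_na = f_na,
                 cl_fraction = cl_fraction, noise_floor = noise_floor,
                 mass_range = mass_range, degradation = degradation,
                 resolution_at_200 = resolution_at_200,
                 n_iso = as.integer(n_iso), seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Internal standard set
#'
#' One quantification standard per lipid class: a short-chain species
#' absent from biological membranes, spiked at a known amount. Exact
#' standard species and amounts are an editable configuration of the
#' platform; the defaults use chain lengths well below each class's
#' endogenous grid and 10 pmol per class.
#'
#' @param registry a `lipid_registry`.
#' @param pmol spiked amount per standard (recycled across classes).
#' @return data.frame (class `standard_set`) with columns `class_name`,
#'   `species` (label) and `pmol`.
#' @export
default_standards <- function(registry = default_registry(), pmol = 10) {
  std_label <- c(
    PC = "PC(28:0)", `PC-O` = "PC-O(28:0)", PE = "PE(28:0)",
    `PE-P` = "PE-P(28:1)", PI = "PI(28:0)", PS = "PS(28:0)",
    PA = "PA(28:0)", `PG/BMP` = "PG/BMP(28:0)", CL = "CL(56:0)",
    LPC = "LPC(14:0)", LPE = "LPE(14:0)", LPI = "LPI(14:0)",
    LPS = "LPS(14:0)", LPG = "LPG(14:0)", LCL = "LCL(42:0)",
    Cer = "Cer(30:1:2)", HexCer = "HexCer(30:1:2)", GM3 = "GM3(30:1:2)",
    Sulf = "Sulf(30:1:2)", SM = "SM(30:1:2)",
    DG = "DG(24:0)", TG = "TG(39:0)", CE = "CE(12:0)")
  cls <- names(registry)
  missing <- setdiff(cls, names(std_label))
  if (length(missing))
    stop("no default standard for class(es): ", paste(missing, collapse = ", "))
  out <- data.frame(class_name = cls,
                    species = unname(std_label[cls]),
                    pmol = rep_len(pmol, length(cls)),
                    row.names = NULL)
  class(out) <- c("standard_set", "data.frame")
  out
}

# TG grid uses even carbons; the TG standard is tri-13:0 (39 carbons), so
# allow odd-carbon standards by bypassing the grid (grids only constrain
# candidate enumeration, which includes standards explicitly).

#' Ground-truth regional lipidome
#'
#' Draws a class-structured lipidome on each class's realistic sum-
#' composition grid. Species concentrations (pmol per ug wet weight) are
#' log-normal around class means; class means follow `class_weights`;
#' membrane-class concentrations are rescaled to sum to
#' `total_membrane` pmol/ug (default 15, i.e. 15 nmol per mg wet weight,
#' a liver-scale membrane lipid density).
#'
#' @param class_weights named non-negative weights per class; defaults to a
#'   realistic mammalian-tissue composition dominated by PC and PE.
#' @param species_per_class number of species drawn per class (recycled or
#'   named vector).
#' @param seed integer seed (profiles are deterministic given the seed).
#' @param total_membrane total membrane-lipid concentration (pmol/ug ww).
#' @param sdlog log-normal spread of species concentrations within a class.
#' @param registry a `lipid_registry`.
#' @return a `region_profile`: data.frame with `species`, `class_name`,
#'   `conc` (pmol/ug ww).
#' @export
make_lipidome <- function(class_weights = default_class_weights(),
                          species_per_class = 9L, seed = 1L,
                          total_membrane = 15, sdlog = 0.7,
                          registry = default_registry()) {
  if (length(class_weights) == 0L) stop("empty class list")
  if (any(class_weights < 0)) stop("class weights must be >= 0")
  unknown <- setdiff(names(class_weights), names(registry))
  if (length(unknown))
    stop("unknown class(es) in weights: ", paste(unknown, collapse = ", "))
  npc <- rep_len(species_per_class, length(class_weights))
  names(npc) <- names(class_weights)
  rng <- .local_rng(seed)
  rows <- list()
  for (cls in names(class_weights)) {
    w <- class_weights[[cls]]
    if (w <= 0) next
    pool <- .grid_species(cls, registry)
    n <- min(npc[[cls]], length(pool))
    picked <- pool[rng$sample(length(pool), n)]
    # concentrations log-normal around the class mean share
    raw <- rng$rlnorm(n, meanlog = 0, sdlog = sdlog)
    conc <- w * raw / sum(raw)
    rows[[cls]] <- data.frame(
      species = vapply(picked, species_label, ""),
      class_name = cls, conc = conc, row.names = NULL)
  }
  prof <- do.call(rbind, c(rows, make.row.names = FALSE))
  memb <- membrane_classes(registry)
  m <- prof$class_name %in% memb
  prof$conc[m] <- prof$conc[m] * total_membrane / sum(prof$conc[m])
  # neutral lipids scale relative to the membrane pool
  if (any(!m) && sum(prof$conc[!m]) > 0) {
    target <- total_membrane * sum(class_weights[unique(prof$class_name[!m])]) /
      sum(class_weights[unique(prof$class_name[m])])
    prof$conc[!m] <- prof$conc[!m] * target / sum(prof$conc[!m])
  }
  structure(prof, class = c("region_profile", "data.frame"))
}

#' Default class weights of the synthetic lipidome
#'
#' Relative class abundances typical of mammalian tissue: PC and PE
#' dominate, acidic glycerophospholipids and sphingolipids are minor, lyso
#' species and PA are trace, neutral lipids form a separate storage pool.
#'
#' @return named numeric vector of weights.
#' @export
default_class_weights <- function() {
  c(PC = 38, "PC-O" = 3, PE = 22, "PE-P" = 4, PI = 7, PS = 6, PA = 0.7,
    "PG/BMP" = 1.2, CL = 3.5, LPC = 0.5, LPE = 0.35, LPI = 0.12,
    LPS = 0.1, LPG = 0.08, LCL = 0.1, Cer = 1.2, HexCer = 1.5, GM3 = 0.6,
    Sulf = 1, SM = 8.5, DG = 1.5, TG = 6, CE = 1)
}

#' Cell-culture ground truth
#'
#' Monolayer scenario: concentrations are expressed per cell and converted
#' to the common pmol/ug scale through the typical cell volume, so the same
#' spot machinery applies. The default 0.07 pmol membrane lipid per cell
#' puts a 5000 um^2 spot (about ten cells) below 1 pmol total membrane
#' lipid, matching the platform's working limit.
#'
#' @param pmol_per_cell total membrane lipid per cell (pmol).
#' @param cell_volume typical cell volume (um^3).
#' @param density tissue density (ug/um^3).
#' @param ... passed to [make_lipidome()].
#' @return a `region_profile`.
#' @export
cell_culture_lipidome <- function(pmol_per_cell = 0.07, cell_volume = 4000,
                                  density = 1e-6, ...) {
  total <- pmol_per_cell / (cell_volume * density)
  make_lipidome(total_membrane = total, ...)
}

# Seed-local RNG: simulations never disturb the caller's RNG state, and
# identical seeds give byte-identical output.
.local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f(...)
  }
  list(rlnorm = with_state(stats::rlnorm),
       rnorm = with_state(stats::rnorm),
       sample = with_state(sample.int))
}

#' Simulate one LMD spot as a polarity-switched peak-list pair
#'
#' Per species, amount (pmol) = concentration x spot wet weight. With
#' `degradation` > 0, that fraction of each diacyl glycerophospholipid that
#' has a lyso partner class is re-routed, half to the lyso species with
#' half the carbons (rounded to the class grid) and half to PA with the
#' same sum composition, conserving total pmol. Each admissible adduct ion
#' then contributes its truncated isotope envelope; the quantification
#' adduct carries the full class response, sodiated PC-type ions carry
#' `f_na` times the protonated response, chloride adducts `cl_fraction`.
#' Intensities are perturbed by log-normal noise of the stated CV (per
#' ion), m/z values are jittered with Gaussian ppm error, centroids closer
#' than one FWHM are merged intensity-weighted, peaks below the noise floor
#' are dropped and the lists restricted to the acquisition mass range.
#' Internal standards are added at their spiked pmol.
#'
#' @param profile a `region_profile` (ground truth, pmol/ug ww).
#' @param spot a `spot_spec`.
#' @param standards a `standard_set` (every class present in the profile
#'   must have one).
#' @param acq an `acquisition_spec`.
#' @param registry a `lipid_registry`.
#' @param sample_id sample identifier stored in the peak lists.
#' @return list with elements `negative` and `positive` (each a `peak_list`
#'   data.frame with columns `mz`, `intensity`), `truth` (data.frame of
#'   species-level ground-truth pmol after degradation routing), `spot`.
#' @export
simulate_spot <- function(profile, spot, standards = default_standards(registry),
                          acq = acquisition_spec(),
                          registry = default_registry(),
                          sample_id = "spot") {
  stopifnot(inherits(profile, "region_profile"), inherits(spot, "spot_spec"))
  missing_std <- setdiff(unique(profile$class_name), standards$class_name)
  if (length(missing_std))
    stop("standards missing for class(es): ",
         paste(missing_std, collapse = ", "))
  ww <- spot_wet_weight(spot)
  truth <- data.frame(species = profile$species,
                      class_name = profile$class_name,
                      pmol = profile$conc * ww)
  if (acq$degradation > 0)
    truth <- .apply_degradation(truth, acq$degradation, registry)
  # spiked standards: amounts independent of spot geometry
  std <- data.frame(species = standards$species,
                    class_name = standards$class_name,
                    pmol = standards$pmol)
  ions_truth <- rbind(truth, std)
  ions_truth <- stats::aggregate(pmol ~ species + class_name, ions_truth, sum)
  rng <- .local_rng(acq$seed + 7L * spot$replicate)
  peaks <- list(negative = list(mz = list(), int = list()),
                positive = list(mz = list(), int = list()))
  sigma <- sqrt(log(1 + acq$intensity_cv^2))
  fp <- .registry_fingerprint(registry)
  for (k in seq_len(nrow(ions_truth))) {
    def <- registry[[ions_truth$class_name[k]]]
    base <- ions_truth$pmol[k]          # response factor 1.0 per class
    for (adduct in .class_adducts(def)) {
      frac <- 1.0
      if (adduct == "[M+Na]+") frac <- acq$f_na
      if (adduct == "[M+Cl]-") frac <- acq$cl_fraction
      ion_int <- base * frac
      if (ion_int <= 0) next
      if (acq$intensity_cv > 0)
        ion_int <- ion_int * rng$rlnorm(1, meanlog = -sigma^2 / 2, sdlog = sigma)
      ion <- .ion_info(ions_truth$species[k], adduct, registry, acq$n_iso, fp)
      mzs <- ion$mz + ion$env$offset / ion$z
      ints <- ion_int * ion$env$abundance / sum(ion$env$abundance)
      if (acq$ppm_sd > 0)
        mzs <- mzs * (1 + rng$rnorm(length(mzs), 0, acq$ppm_sd) * 1e-6)
      pol <- .adduct_polarity(adduct)
      n <- length(peaks[[pol]]$mz) + 1L
      peaks[[pol]]$mz[[n]] <- mzs
      peaks[[pol]]$int[[n]] <- ints
    }
  }
  out <- lapply(c(negative = "negative", positive = "positive"), function(pol) {
    df <- data.frame(mz = unlist(peaks[[pol]]$mz) %||% numeric(0),
                     intensity = unlist(peaks[[pol]]$int) %||% numeric(0))
    df <- df[order(df$mz), , drop = FALSE]
    df <- .merge_centroids(df, acq$resolution_at_200)
    df <- df[df$intensity >= acq$noise_floor &
             df$mz >= acq$mass_range[1] & df$mz <= acq$mass_range[2], ,
             drop = FALSE]
    peak_list(df$mz, df$intensity, polarity = pol, sample_id = sample_id)
  })
  list(negative = out$negative, positive = out$positive,
       truth = ions_truth, spot = spot)
}

# Laser-ablation degradation: fraction delta of each diacyl
# glycerophospholipid with a lyso partner moves half to lyso(C/2 rounded
# to the class grid, floor(DB/2)) and half to PA(C:DB). Total pmol over
# parent + lyso + PA is conserved.
.apply_degradation <- function(truth, delta, registry) {
  add <- list()
  for (k in seq_len(nrow(truth))) {
    cls <- truth$class_name[k]
    def <- registry[[cls]]
    if (is.na(def$lyso_partner) || def$chains != 2L) next
    sp <- parse_sum_formula(truth$species[k], registry)
    moved <- truth$pmol[k] * delta
    truth$pmol[k] <- truth$pmol[k] - moved
    lg <- registry[[def$lyso_partner]]$grid
    lc <- round(sp$carbons / 2)
    lc <- max(lg$c_range[1], min(lg$c_range[2], lc + (lc %% lg$c_by)))
    ldb <- min(sp$double_bonds %/% 2L, lg$db_range[2])
    lyso <- species_label(lipid_species(def$lyso_partner, lc, ldb,
                                        NULL, registry))
    pa <- species_label(lipid_species("PA", sp$carbons, sp$double_bonds,
                                      NULL, registry))
    add[[length(add) + 1L]] <- data.frame(
      species = c(lyso, pa),
      class_name = c(def$lyso_partner, "PA"),
      pmol = c(moved / 2, moved / 2))
  }
  out <- rbind(truth, do.call(rbind, add))
  stats::aggregate(pmol ~ species + class_name, out, sum)
}

# Merge centroids closer than one FWHM (unresolved at the instrument's
# resolving power) into a single intensity-weighted centroid.
.merge_centroids <- function(df, resolution_at_200) {
  n <- nrow(df)
  if (n < 2L) return(df)
  gap <- diff(df$mz)
  fw <- .MERGE_FRAC * peak_fwhm(df$mz[-n], resolution_at_200)
  grp <- cumsum(c(1L, as.integer(gap >= fw)))
  if (max(grp) == n) return(df)
  grp <- factor(grp, levels = unique(grp))   # keep ascending-m/z order
  wsum <- tapply(df$mz * df$intensity, grp, sum)
  isum <- tapply(df$intensity, grp, sum)
  data.frame(mz = as.numeric(wsum / isum), intensity = as.numeric(isum))
}

#' Construct a centroid peak list
#'
#' @param mz m/z values (will be sorted; must end up strictly increasing).
#' @param intensity positive intensities.
#' @param polarity `"positive"` or `"negative"`.
#' @param sample_id sample identifier.
#' @return a `peak_list` data.frame with attributes `polarity`, `sample_id`.
#' @export
peak_list <- function(mz, intensity, polarity, sample_id = "sample") {
  polarity <- match.arg(polarity, c("negative", "positive"))
  stopifnot(length(mz) == length(intensity))
  if (any(intensity <= 0)) stop("intensities must be > 0")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) stop("m/z values must be strictly increasing")
  structure(data.frame(mz = mz, intensity = intensity),
            polarity = polarity, sample_id = sample_id,
            class = c("peak_list", "data.frame"))
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list> ", attr(x, "sample_id"), " [", attr(x, "polarity"),
      "], ", nrow(x), " centroids",
      if (nrow(x)) sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Simulate a dilution-style area series from homogeneous tissue
#'
#' One spot pair per (area, replicate), all drawn from the same ground-truth
#' profile: the linearity-of-quantification experiment of the platform
#' (default areas 5, 10, 20, 40, 80, 160 x 10^3 um^2, n = 4).
#'
#' @param profile a `region_profile`.
#' @param areas dissected areas in um^2, sorted ascending.
#' @param replicates replicates per area.
#' @param acq an `acquisition_spec`; each spot gets a distinct sub-seed.
#' @param standards,registry as in [simulate_spot()].
#' @param thickness section thickness (um).
#' @return list of per-spot results as returned by [simulate_spot()], with
#'   a `manifest` data.frame attribute (sample_id, area, replicate).
#' @export
simulate_area_series <- function(profile,
                                 areas = c(5, 10, 20, 40, 80, 160) * 1e3,
                                 replicates = 4L,
                                 acq = acquisition_spec(),
                                 standards = default_standards(registry),
                                 registry = default_registry(),
                                 thickness = 10) {
  stopifnot(all(areas > 0), !is.unsorted(areas))
  out <- list()
  manifest <- list()
  i <- 0L
  for (a in areas) for (r in seq_len(replicates)) {
    i <- i + 1L
    id <- sprintf("area%06d_rep%d", as.integer(a), r)
    sp <- spot_spec(a, thickness = thickness, replicate = i)
    acq_i <- acq
    acq_i$seed <- acq$seed + 1000L * i
    out[[id]] <- simulate_spot(profile, sp, standards, acq_i, registry,
                               sample_id = id)
    manifest[[i]] <- data.frame(sample_id = id, area = a, replicate = r)
  }
  attr(out, "manifest") <- do.call(rbind, manifest)
  out
}

#' Simulate a multi-region ROI experiment
#'
#' ROI samples tagged with region labels and polygon geometry; ROIs that
#' share an anatomical region share a ground-truth profile, replicates
#' emulate successive sections. The default plan mirrors a hippocampus-like
#' layout: 11 ROIs in 6 anatomical groups with areas between 50,000 and
#' 130,000 um^2.
#'
#' @param region_profiles named list of `region_profile`s (>= 2), one per
#'   anatomical region.
#' @param roi_plan data.frame with columns `roi` (id), `region` (name into
#'   `region_profiles`), `area` (um^2), and optionally `cx`, `cy` (centroid,
#'   um). Defaults to [default_roi_plan()] for the given profiles.
#' @param replicates successive-section replicates per ROI (default 3).
#' @param acq an `acquisition_spec`.
#' @param standards,registry as in [simulate_spot()].
#' @return list of per-sample spot results with a `manifest` attribute
#'   (sample_id, roi, region, area, replicate, cx, cy).
#' @export
simulate_regions <- function(region_profiles, roi_plan = NULL,
                             replicates = 3L,
                             acq = acquisition_spec(),
                             standards = default_standards(registry),
                             registry = default_registry()) {
  if (length(region_profiles) < 2L) stop("need >= 2 region profiles")
  if (is.null(roi_plan)) roi_plan <- default_roi_plan(names(region_profiles))
  stopifnot(all(roi_plan$region %in% names(region_profiles)))
  if (is.null(roi_plan$cx)) {
    side <- ceiling(sqrt(nrow(roi_plan)))
    roi_plan$cx <- 400 * ((seq_len(nrow(roi_plan)) - 1) %% side)
    roi_plan$cy <- 400 * ((seq_len(nrow(roi_plan)) - 1) %/% side)
  }
  out <- list()
  manifest <- list()
  i <- 0L
  for (k in seq_len(nrow(roi_plan))) for (r in seq_len(replicates)) {
    i <- i + 1L
    id <- sprintf("roi%02d_sec%d", roi_plan$roi[k], r)
    sp <- spot_spec(roi_plan$area[k], region = roi_plan$region[k],
                    replicate = i)
    acq_i <- acq
    acq_i$seed <- acq$seed + 1000L * i
    out[[id]] <- simulate_spot(region_profiles[[roi_plan$region[k]]], sp,
                               standards, acq_i, registry, sample_id = id)
    manifest[[i]] <- data.frame(sample_id = id, roi = roi_plan$roi[k],
                                region = roi_plan$region[k],
                                area = roi_plan$area[k], replicate = r,
                                cx = roi_plan$cx[k], cy = roi_plan$cy[k])
  }
  attr(out, "manifest") <- do.call(rbind, manifest)
  out
}

#' Default 11-ROI plan over anatomical groups
#'
#' Distributes 11 ROIs over the supplied regions following the grouping
#' sizes 2, 3, 1, 1, 1, 3 when six regions are given (a hippocampus-like
#' layout: paired granule-cell ROIs, a three-ROI pyramidal layer, single
#' deviant/molecular/lacunosum ROIs and a three-ROI stratum radiatum), or
#' round-robin otherwise. Areas are spread over 50,000-130,000 um^2.
#'
#' @param regions character vector of region names.
#' @return data.frame with `roi`, `region`, `area`.
#' @export
default_roi_plan <- function(regions) {
  n_roi <- 11L
  assign_regions <- if (length(regions) == 6L)
    rep(regions, times = c(2L, 3L, 1L, 1L, 1L, 3L))
  else
    regions[1L + (seq_len(n_roi) - 1L) %% length(regions)]
  data.frame(roi = seq_len(n_roi),
             region = assign_regions,
             area = round(seq(50000, 130000, length.out = n_roi)))
}

#' Perturb a ground-truth profile into a related regional profile
#'
#' Keeps the species set, rescales classes by `class_factors` and jitters
#' species concentrations log-normally; membrane totals are preserved.
#' Used to build anatomically distinct but compositionally related regions.
#'
#' @param profile a `region_profile`.
#' @param class_factors named multipliers per class (missing classes keep 1).
#' @param species_sdlog log-normal jitter of individual species (default 0.3).
#' @param seed integer seed.
#' @param registry a `lipid_registry`.
#' @return a `region_profile`.
#' @export
perturb_profile <- function(profile, class_factors = c(), species_sdlog = 0.3,
                            seed = 1L, registry = default_registry()) {
  rng <- .local_rng(seed)
  fac <- rep(1, nrow(profile))
  hit <- profile$class_name %in% names(class_factors)
  fac[hit] <- unlist(class_factors[profile$class_name[hit]])
  jit <- rng$rlnorm(nrow(profile), 0, species_sdlog)
  out <- profile
  memb <- profile$class_name %in% membrane_classes(registry)
  tot0 <- sum(profile$conc[memb])
  out$conc <- profile$conc * fac * jit
  out$conc[memb] <- out$conc[memb] * tot0 / sum(out$conc[memb])
  out
}
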