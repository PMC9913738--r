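# Independent mass-arithmetic oracle --------------------------------------
# Deliberately separate from the package implementation: its own atomic
# mass constants (CODATA/AME-style, more digits), its own formula parser
# and its own adduct algebra written in terms of proton/electron masses.

ORACLE_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                 O = 15.9949146196, P = 30.97376163, S = 31.97207100,
                 Na = 22.9897692809, Cl = 34.96885268)
ORACLE_ELECTRON <- 0.00054857991
ORACLE_PROTON <- ORACLE_MASS[["H"]] - ORACLE_ELECTRON

oracle_mass <- function(formula) {
  toks <- regmatches(formula,
                     gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  sum(vapply(toks, function(t) {
    el <- gsub("[0-9]", "", t)
    n <- gsub("[A-Za-z]", "", t)
    ORACLE_MASS[[el]] * if (nzchar(n)) as.integer(n) else 1L
  }, 0))
}

oracle_mz <- function(formula, adduct) {
  M <- oracle_mass(formula)
  switch(adduct,
    "[M+H]+"   = M + ORACLE_PROTON,
    "[M+Na]+"  = M + ORACLE_MASS[["Na"]] - ORACLE_ELECTRON,
    "[M+NH4]+" = M + ORACLE_MASS[["N"]] + 4 * ORACLE_MASS[["H"]] -
                 ORACLE_ELECTRON,
    "[M-H]-"   = M - ORACLE_PROTON,
    "[M-2H]2-" = (M - 2 * ORACLE_PROTON) / 2,
    "[M+Cl]-"  = M + ORACLE_MASS[["Cl"]] + ORACLE_ELECTRON,
    stop("oracle: unknown adduct ", adduct))
}

# Literature molecular formulas for representative species of every class
# (sum-composition level, standard lipid-structure database entries).
LITERATURE_FORMULAS <- c(
  "PC(34:2)"      = "C42H80NO8P",
  "PC(38:6)"      = "C46H80NO8P",
  "PC-O(34:1)"    = "C42H84NO7P",
  "PE(34:1)"      = "C39H76NO8P",
  "PE-P(34:1)"    = "C39H76NO7P",
  "PI(34:1)"      = "C43H81O13P",
  "PS(34:1)"      = "C40H76NO10P",
  "PA(34:1)"      = "C37H71O8P",
  "PG/BMP(34:1)"  = "C40H77O10P",
  "CL(72:8)"      = "C81H142O17P2",
  "LPC(16:0)"     = "C24H50NO7P",
  "LPE(18:1)"     = "C23H46NO7P",
  "Cer(34:1:2)"   = "C34H67NO3",
  "HexCer(34:1:2)" = "C40H77NO8",
  "GM3(34:1:2)"   = "C57H104N2O21",
  "Sulf(42:2:2)"  = "C48H91NO11S",
  "SM(34:1:2)"    = "C39H79N2O6P",
  "SM(36:1:2)"    = "C41H83N2O6P",
  "DG(34:1)"      = "C37H70O5",
  "TG(52:2)"      = "C55H102O6",
  "CE(18:1)"      = "C45H78O2"
)

# Shared fixtures ----------------------------------------------------------

noiseless_acq <- function(seed = 1L, ...) {
  acquisition_spec(ppm_sd = 0, intensity_cv = 0, seed = seed, ...)
}

# A small hand-specified ground-truth profile.
make_profile <- function(species, conc, registry = default_registry()) {
  cls <- vapply(species, function(s)
    parse_sum_formula(s, registry)$class_name, "")
  structure(data.frame(species = species, class_name = unname(cls),
                       conc = conc),
            class = c("region_profile", "data.frame"))
}

# Registry variant quantifying PC from the protonated ion in positive mode
# (the configuration in which the sodiated-adduct overlap hits
# quantification directly).
registry_pc_positive <- function() {
  reg <- default_registry()
  reg$PC$quant_polarity <- "positive"
  reg$PC$quant_adduct <- "[M+H]+"
  reg$PC$extra_adducts <- c("[M+Cl]-", "[M+Na]+")
  reg
}

pc_standard <- function(registry = default_registry()) {
  std <- default_standards(registry)
  std[std$class_name == "PC", , drop = FALSE]
}

# Forward-model detectability oracle --------------------------------------
# From the ground-truth amounts alone, predict which quantification ions
# survive centroiding as identifiable monoisotopic peaks: their cluster of
# unresolvable predicted peaks must lie inside the acquisition window, sum
# above the noise floor, and have an intensity-weighted centroid within the
# mass tolerance of the theoretical position (a centroid dragged away by a
# fused interference is no longer that species' peak). Contested clusters
# go to the nearest candidate, like the matcher's declared rule.
expected_detectable <- function(truth, acq, registry = default_registry(),
                                tol_ppm = 2) {
  qa <- vapply(registry, `[[`, "", "quant_adduct")
  out <- list()
  for (pol in c("negative", "positive")) {
    rows <- list()
    for (k in seq_len(nrow(truth))) {
      def <- registry[[truth$class_name[k]]]
      for (a in unique(c(def$quant_adduct, def$extra_adducts))) {
        if (spotlipids:::.adduct_polarity(a) != pol) next
        frac <- switch(a, "[M+Na]+" = acq$f_na, "[M+Cl]-" = acq$cl_fraction, 1)
        if (frac <= 0) next
        info <- spotlipids:::.ion_info(truth$species[k], a, registry,
                                       acq$n_iso)
        rows[[length(rows) + 1L]] <- data.frame(
          species = truth$species[k], adduct = a,
          pos = info$mz + info$env$offset / info$z,
          int = truth$pmol[k] * frac * info$env$abundance /
            sum(info$env$abundance),
          mono = info$env$n13c == 0 & info$env$n37cl == 0,
          quant = a == qa[[truth$class_name[k]]])
      }
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$pos), ]
    gap <- diff(tab$pos)
    fw <- spotlipids:::.MERGE_FRAC *
      peak_fwhm(tab$pos[-nrow(tab)], acq$resolution_at_200)
    tab$cluster <- cumsum(c(1L, as.integer(gap >= fw)))
    cent <- tapply(tab$pos * tab$int, tab$cluster, sum) /
      tapply(tab$int, tab$cluster, sum)
    tot <- tapply(tab$int, tab$cluster, sum)
    m <- tab[tab$mono & tab$quant, ]
    m$centroid <- cent[as.character(m$cluster)]
    m$total <- tot[as.character(m$cluster)]
    m$ppm <- abs(m$centroid - m$pos) / m$pos * 1e6
    m <- m[m$total >= acq$noise_floor &
           m$centroid >= acq$mass_range[1] &
           m$centroid <= acq$mass_range[2] &
           m$ppm <= tol_ppm, ]
    # contested clusters: nearest candidate wins
    m <- m[order(m$cluster, m$ppm), ]
    m <- m[!duplicated(m$cluster), ]
    out[[pol]] <- m[c("species", "adduct")]
  }
  do.call(rbind, out)
}

# Membrane-amounts long table from a quantified dataset, for linearity fits.
membrane_amounts <- function(qs) {
  man <- attr(qs, "manifest")
  do.call(rbind, lapply(seq_along(qs), function(i) {
    q <- qs[[i]]
    data.frame(area = man$area[i], replicate = man$replicate[i],
               species = q$species[q$membrane], pmol = q$pmol[q$membrane])
  }))
}

# Median membrane-total R^2 of a simulated area series over several seeds.
area_series_r2 <- function(profile, seeds, intensity_cv,
                           registry = default_registry()) {
  std <- default_standards(registry)
  cand <- list(
    negative = build_candidates(registry, "negative", standards = std),
    positive = build_candidates(registry, "positive", standards = std))
  r2 <- vapply(seeds, function(s) {
    ser <- simulate_area_series(
      profile, acq = acquisition_spec(intensity_cv = intensity_cv, seed = s),
      registry = registry)
    qs <- quantify_dataset(ser, std, registry, candidates = cand)
    fit <- linearity_fit(membrane_amounts(qs))
    attr(fit, "membrane_fit")$r_squared
  }, 0)
  stats::median(r2)
}
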