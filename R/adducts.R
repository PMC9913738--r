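# Adduct arithmetic -------------------------------------------------------
#
# m/z contract for an ion of neutral monoisotopic mass M, adduct element
# delta D (signed), charge z and electron mass m_e:
#
#     m/z = (M + mass(D) - z * m_e) / |z|
#
# so protonation both adds a hydrogen atom mass and removes an electron.

.ADDUCTS <- list(
  "[M-H]-"   = list(charge = -1L, delta = c(H = -1L)),
  "[M-2H]2-" = list(charge = -2L, delta = c(H = -2L)),
  "[M+Cl]-"  = list(charge = -1L, delta = c(Cl = 1L)),
  "[M+H]+"   = list(charge = +1L, delta = c(H = 1L)),
  "[M+Na]+"  = list(charge = +1L, delta = c(Na = 1L)),
  "[M+NH4]+" = list(charge = +1L, delta = c(N = 1L, H = 4L))
)

#' Supported adduct types
#'
#' @return data.frame of adduct name, charge and polarity.
#' @export
adduct_types <- function() {
  data.frame(adduct = names(.ADDUCTS),
             charge = vapply(.ADDUCTS, `[[`, 0L, "charge"),
             polarity = ifelse(vapply(.ADDUCTS, `[[`, 0L, "charge") > 0,
                               "positive", "negative"),
             row.names = NULL)
}

.adduct_def <- function(adduct) {
  d <- .ADDUCTS[[adduct]]
  if (is.null(d)) stop("unknown adduct type: ", adduct)
  d
}

.adduct_polarity <- function(adduct) {
  if (.adduct_def(adduct)$charge > 0) "positive" else "negative"
}

# Signed mass contribution of the adduct's element delta.
.adduct_delta_mass <- function(adduct) {
  d <- .adduct_def(adduct)$delta
  sum(.ATOMIC_MASS[names(d)] * d)
}

# Admissible adducts for a class = quantification adduct + extras.
.class_adducts <- function(def) unique(c(def$quant_adduct, def$extra_adducts))

#' Theoretical m/z of a species/adduct ion
#'
#' Computes the monoisotopic m/z of the given adduct ion of a lipid species
#' from the embedded atomic mass table, with electron-mass correction per
#' elementary charge. The adduct must be admissible for the species' class
#' (its quantification adduct or one of its listed extra adducts) unless
#' `check_admissible = FALSE`.
#'
#' @param species a `lipid_species` or label string.
#' @param adduct adduct name, one of `adduct_types()$adduct`.
#' @param registry a `lipid_registry`.
#' @param check_admissible verify the class/adduct pairing against the
#'   registry (default TRUE).
#' @return m/z in Da (positive scalar).
#' @examples
#' adduct_mz("PC(34:2)", "[M+H]+")                       # 758.5694
#' adduct_mz("PC(36:5)", "[M+H]+") -
#'   adduct_mz("PC(34:2)", "[M+Na]+")                    # 0.0024
#' @export
adduct_mz <- function(species, adduct, registry = default_registry(),
                      check_admissible = TRUE) {
  if (is.character(species)) species <- parse_sum_formula(species, registry)
  def <- .adduct_def(adduct)
  if (check_admissible) {
    cls <- registry[[species$class_name]]
    if (!is.null(cls) && !(adduct %in% .class_adducts(cls)))
      stop("adduct ", adduct, " not admissible for class ", species$class_name)
  }
  M <- monoisotopic_mass(composition_of(species, registry))
  (M + .adduct_delta_mass(adduct) - def$charge * .ELECTRON_MASS) /
    abs(def$charge)
}

# Memoized per-(species, adduct) ion chemistry. The cache key includes a
# registry fingerprint (class names + backbone formulas) so edited
# registries never serve stale masses; everything cached is a pure
# function of (label, adduct, registry backbones, n_iso).
.ion_cache <- new.env(parent = emptyenv())

.registry_fingerprint <- function(registry) {
  paste(names(registry),
        vapply(registry, function(d) format_formula(d$backbone), ""),
        collapse = "|")
}

.ion_info <- function(label, adduct, registry, n_iso,
                      fp = .registry_fingerprint(registry)) {
  key <- paste(fp, label, adduct, n_iso, sep = "\r")
  hit <- .ion_cache[[key]]
  if (!is.null(hit)) return(hit)
  sp <- parse_sum_formula(label, registry)
  env <- isotope_distribution(.ion_composition(sp, adduct, registry), n_iso)
  val <- list(species = sp,
              mz = adduct_mz(sp, adduct, registry, check_admissible = FALSE),
              z = abs(.adduct_def(adduct)$charge),
              env = env,
              mono_frac = env$abundance[env$n13c == 0 & env$n37cl == 0] /
                sum(env$abundance))
  assign(key, val, envir = .ion_cache)
  val
}

# Composition of the full ion (neutral + adduct elements); negative deltas
# (proton loss) subtract. Used for isotope envelopes, where the adduct's
# own atoms (notably Cl) matter.
.ion_composition <- function(species, adduct, registry) {
  comp <- composition_of(species, registry)
  d <- .adduct_def(adduct)$delta
  add <- d[d > 0]
  rem <- -d[d < 0]
  if (length(add))
    comp <- comp + do.call(elemental_composition, as.list(add))
  if (length(rem))
    comp <- comp - do.call(elemental_composition, as.list(rem))
  comp
}
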