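# Sum-composition species grammar ----------------------------------------

#' Construct a lipid species at sum-composition level
#'
#' A species is a class plus total chain carbons and double bonds, with a
#' third hydroxyl index for sphingolipids: the annotation level of
#' high-resolution MS1 shotgun lipidomics, e.g. `PC(38:6)` (total carbons :
#' total double bonds over all chains) or `SM(36:1:2)` (carbons : double
#' bonds : hydroxyls summed over long-chain base and fatty acid).
#'
#' @param class_name registry class name, e.g. `"PC"`, `"SM"`, `"PG/BMP"`.
#' @param carbons total chain carbons (integer, >= 2).
#' @param double_bonds total chain double bonds (integer, >= 0).
#' @param hydroxyls total hydroxyls (sphingolipid classes only).
#' @param registry a `lipid_registry`; defaults to [default_registry()].
#' @return an object of class `lipid_species`.
#' @examples
#' lipid_species("PC", 38, 6)
#' lipid_species("SM", 36, 1, 2)
#' @export
lipid_species <- function(class_name, carbons, double_bonds, hydroxyls = NULL,
                          registry = default_registry()) {
  def <- registry[[class_name]]
  if (is.null(def)) stop("unknown lipid class: ", class_name)
  if (!is.numeric(carbons) || carbons != round(carbons) || carbons < 2)
    stop("total carbons must be an integer >= 2")
  if (!is.numeric(double_bonds) || double_bonds != round(double_bonds) ||
      double_bonds < 0)
    stop("double bonds must be a non-negative integer")
  if (def$sphingoid) {
    if (is.null(hydroxyls))
      stop("sphingolipid class ", class_name, " needs a hydroxyl index")
    if (!is.numeric(hydroxyls) || hydroxyls != round(hydroxyls) || hydroxyls < 0)
      stop("hydroxyls must be a non-negative integer")
  } else {
    if (!is.null(hydroxyls))
      stop("class ", class_name, " takes two indices (C:DB), not three")
    hydroxyls <- 0L
  }
  structure(list(class_name = class_name,
                 carbons = as.integer(carbons),
                 double_bonds = as.integer(double_bonds),
                 hydroxyls = as.integer(hydroxyls),
                 sphingoid = def$sphingoid),
            class = "lipid_species")
}

#' Canonical label of a species
#'
#' Glycerolipids print two indices `class(C:DB)`, sphingolipids three
#' `class(C:DB:OH)`. Labels round-trip exactly through
#' [parse_sum_formula()].
#'
#' @param species a `lipid_species`.
#' @export
species_label <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  idx <- if (species$sphingoid)
    paste(species$carbons, species$double_bonds, species$hydroxyls, sep = ":")
  else
    paste(species$carbons, species$double_bonds, sep = ":")
  paste0(species$class_name, "(", idx, ")")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(species_label(x), " [", format_formula(composition_of(x)), "]\n", sep = "")
  invisible(x)
}

#' @export
format.lipid_species <- function(x, ...) species_label(x)

#' Parse a sum-composition label
#'
#' Inverse of [species_label()]: `"PC(38:6)"` or `"SM(36:1:2)"` (whitespace
#' tolerated) back to a [lipid_species()]. Errors on unknown classes, wrong
#' index counts for the class family, or non-integer/negative indices.
#'
#' @param label character label.
#' @param registry a `lipid_registry`.
#' @return a `lipid_species` whose canonical label equals the
#'   whitespace-normalized input.
#' @examples
#' parse_sum_formula("PC(38:6)")
#' parse_sum_formula("SM(36:1:2)")
#' @export
parse_sum_formula <- function(label, registry = default_registry()) {
  stopifnot(is.character(label), length(label) == 1L)
  lab <- gsub("[[:space:]]", "", label)
  if (!nzchar(lab)) stop("empty species label")
  m <- regmatches(lab, regexec("^(.+)\\(([0-9]+):([0-9]+)(?::([0-9]+))?\\)$",
                               lab, perl = TRUE))[[1]]
  if (length(m) == 0L)
    stop("malformed species label: ", label)
  cls <- m[2]
  if (is.null(registry[[cls]])) stop("unknown lipid class: ", cls)
  oh <- if (nzchar(m[5])) as.integer(m[5]) else NULL
  if (registry[[cls]]$sphingoid && is.null(oh))
    stop("sphingolipid class ", cls, " requires three indices (C:DB:OH)")
  if (!registry[[cls]]$sphingoid && !is.null(oh))
    stop("class ", cls, " takes two indices (C:DB)")
  lipid_species(cls, as.integer(m[3]), as.integer(m[4]), oh, registry)
}

#' Elemental composition of a species
#'
#' Backbone contribution of the class plus the chain contribution: each
#' chain carbon adds CH2, each double bond removes H2, each sphingolipid
#' hydroxyl adds one O. Errors if the arithmetic would produce a negative
#' element count (an impossible species, e.g. more double bonds than the
#' chains can carry).
#'
#' @param species a `lipid_species` (or a label string).
#' @param registry a `lipid_registry`.
#' @return an `elemental_composition`.
#' @examples
#' composition_of(parse_sum_formula("PC(34:2)"))  # C42H80NO8P
#' @export
composition_of <- function(species, registry = default_registry()) {
  if (is.character(species)) species <- parse_sum_formula(species, registry)
  stopifnot(inherits(species, "lipid_species"))
  def <- registry[[species$class_name]]
  if (is.null(def)) stop("species class not in registry: ", species$class_name)
  chain <- elemental_composition(C = species$carbons,
                                 H = 2L * species$carbons,
                                 O = species$hydroxyls)
  minus_h <- elemental_composition(H = 2L * species$double_bonds)
  def$backbone + chain - minus_h
}

# Enumerate the registry grid of a class as species objects.
.grid_species <- function(class_name, registry,
                          c_range = NULL, db_range = NULL) {
  def <- registry[[class_name]]
  g <- def$grid
  cr <- if (is.null(c_range)) g$c_range else c_range
  dr <- if (is.null(db_range)) g$db_range else db_range
  if (cr[1] > cr[2] || dr[1] > dr[2]) return(list())
  cs <- seq(cr[1], cr[2], by = g$c_by)
  dbs <- seq(dr[1], dr[2])
  ohs <- if (def$sphingoid) g$oh else 0L
  out <- list()
  for (C in cs) for (D in dbs) for (OH in ohs) {
    sp <- lipid_species(class_name, C, D,
                        if (def$sphingoid) OH else NULL, registry)
    out[[length(out) + 1L]] <- sp
  }
  out
}
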