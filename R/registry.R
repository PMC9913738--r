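# Lipid class registry ---------------------------------------------------
#
# Each class is described by the elemental contribution of its "backbone"
# (the hypothetical member with zero chain carbons, zero double bonds and,
# for sphingolipids, zero hydroxyls), the number of chains, a sphingoid
# flag (which switches the label grammar to the three-index C:DB:OH form
# and makes the OH index add oxygens), its quantification polarity/adduct,
# any additional detectable adducts, whether it counts as a membrane lipid
# (glycerophospho- or sphingolipid) for the mol% denominator, and a
# realistic sum-composition grid used by the candidate index and the
# synthetic generator.
#
# Backbone contributions are derived from standard condensation chemistry
# (glycerophosphate + head group + acyls - waters) and validated in the
# test-suite against literature molecular formulas. The per-carbon chain
# contribution is CH2, each double bond removes H2, each sphingolipid
# hydroxyl adds one O.
#
# Isomeric pairs that high-resolution MS1 cannot distinguish are stored
# once and quantified collectively: PC-O(x:y) with PC-P(x:y-1),
# PE-P(x:y) with PE-O(x:y+1), and PG with BMP (merged class "PG/BMP").

.class_def <- function(name, backbone, chains, sphingoid, quant_polarity,
                       quant_adduct, extra_adducts, membrane, grid,
                       lyso_partner = NA_character_) {
  list(name = name, backbone = backbone, chains = chains,
       sphingoid = sphingoid, quant_polarity = quant_polarity,
       quant_adduct = quant_adduct, extra_adducts = extra_adducts,
       membrane = membrane, grid = grid, lyso_partner = lyso_partner)
}

.grid <- function(c_min, c_max, c_by = 2L, db_min = 0L, db_max = 6L, oh = integer(0)) {
  list(c_range = as.integer(c(c_min, c_max)), c_by = as.integer(c_by),
       db_range = as.integer(c(db_min, db_max)), oh = as.integer(oh))
}

#' Default lipid class registry
#'
#' Builds the registry of the 23 supported lipid classes with their backbone
#' elemental contributions, chain counts, quantification polarity and adduct
#' (negative mode for glycerophospholipids, their lyso forms and most
#' sphingolipids; positive mode for SM and the neutral lipids DG/TG/CE;
#' PC/PC-O are quantified from their chloride adducts in negative mode and
#' additionally observed as protonated/sodiated ions in positive mode),
#' additional detectable adducts, membrane-lipid status and a realistic
#' sum-composition grid.
#'
#' The registry is an ordinary named list and is fully editable; it can be
#' round-tripped through YAML with [write_registry()] / [read_registry()].
#'
#' @return a named list of class definitions, class `lipid_registry`.
#' @examples
#' reg <- default_registry()
#' names(reg)
#' reg$PC$quant_adduct
#' @export
default_registry <- function() {
  cmp <- elemental_composition
  defs <- list(
    # Glycerophospholipids (diacyl): backbone = glycerophosphate head-group
    # core carrying both ester groups.
    .class_def("PC", cmp(C = 8, H = 16, N = 1, O = 8, P = 1), 2L, FALSE,
               "negative", "[M+Cl]-", c("[M+H]+", "[M+Na]+"), TRUE,
               .grid(30, 40, 2, 0, 6), "LPC"),
    .class_def("PC-O", cmp(C = 8, H = 18, N = 1, O = 7, P = 1), 2L, FALSE,
               "negative", "[M+Cl]-", c("[M+H]+", "[M+Na]+"), TRUE,
               .grid(32, 38, 2, 0, 5)),
    .class_def("PE", cmp(C = 5, H = 10, N = 1, O = 8, P = 1), 2L, FALSE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(32, 40, 2, 0, 6), "LPE"),
    .class_def("PE-P", cmp(C = 5, H = 10, N = 1, O = 7, P = 1), 2L, FALSE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(32, 40, 2, 1, 6)),
    .class_def("PI", cmp(C = 9, H = 15, O = 13, P = 1), 2L, FALSE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(32, 40, 2, 0, 6), "LPI"),
    .class_def("PS", cmp(C = 6, H = 10, N = 1, O = 10, P = 1), 2L, FALSE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(32, 40, 2, 0, 6), "LPS"),
    .class_def("PA", cmp(C = 3, H = 5, O = 8, P = 1), 2L, FALSE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(32, 40, 2, 0, 6)),
    .class_def("PG/BMP", cmp(C = 6, H = 11, O = 10, P = 1), 2L, FALSE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(32, 44, 2, 0, 12), "LPG"),
    .class_def("CL", cmp(C = 9, H = 14, O = 17, P = 2), 4L, FALSE,
               "negative", "[M-2H]2-", character(0), TRUE,
               .grid(68, 76, 2, 4, 10), "LCL"),
    # Lyso glycerophospholipids: one acyl removed (backbone = diacyl
    # backbone - O + H2).
    .class_def("LPC", cmp(C = 8, H = 18, N = 1, O = 7, P = 1), 1L, FALSE,
               "negative", "[M+Cl]-", character(0), TRUE,
               .grid(16, 22, 2, 0, 4)),
    .class_def("LPE", cmp(C = 5, H = 12, N = 1, O = 7, P = 1), 1L, FALSE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(16, 22, 2, 0, 4)),
    .class_def("LPI", cmp(C = 9, H = 17, O = 12, P = 1), 1L, FALSE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(16, 22, 2, 0, 4)),
    .class_def("LPS", cmp(C = 6, H = 12, N = 1, O = 9, P = 1), 1L, FALSE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(16, 22, 2, 0, 4)),
    .class_def("LPG", cmp(C = 6, H = 13, O = 9, P = 1), 1L, FALSE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(16, 22, 2, 0, 4)),
    .class_def("LCL", cmp(C = 9, H = 16, O = 16, P = 2), 3L, FALSE,
               "negative", "[M-2H]2-", character(0), TRUE,
               .grid(54, 60, 2, 2, 6)),
    # Sphingolipids: three-index grammar C:DB:OH; OH adds oxygens.
    .class_def("Cer", cmp(H = 1, N = 1, O = 1), 2L, TRUE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(32, 42, 2, 1, 2, oh = 2L)),
    .class_def("HexCer", cmp(C = 6, H = 11, N = 1, O = 6), 2L, TRUE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(32, 42, 2, 1, 2, oh = 2L)),
    .class_def("GM3", cmp(C = 23, H = 38, N = 2, O = 19), 2L, TRUE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(32, 42, 2, 1, 2, oh = 2L)),
    .class_def("Sulf", cmp(C = 6, H = 11, N = 1, O = 9, S = 1), 2L, TRUE,
               "negative", "[M-H]-", character(0), TRUE,
               .grid(32, 42, 2, 1, 2, oh = 2L)),
    .class_def("SM", cmp(C = 5, H = 13, N = 2, O = 4, P = 1), 2L, TRUE,
               "positive", "[M+H]+", character(0), TRUE,
               .grid(32, 42, 2, 1, 2, oh = 2L)),
    # Neutral storage lipids: ammoniated ions in positive mode; excluded
    # from the membrane mol% denominator.
    .class_def("DG", cmp(C = 3, H = 4, O = 5), 2L, FALSE,
               "positive", "[M+NH4]+", character(0), FALSE,
               .grid(30, 38, 2, 0, 4)),
    .class_def("TG", cmp(C = 3, H = 2, O = 6), 3L, FALSE,
               "positive", "[M+NH4]+", character(0), FALSE,
               .grid(48, 56, 2, 0, 6)),
    .class_def("CE", cmp(C = 27, H = 44, O = 2), 1L, FALSE,
               "positive", "[M+NH4]+", character(0), FALSE,
               .grid(14, 20, 2, 0, 2))
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  structure(defs, class = "lipid_registry")
}

#' @export
print.lipid_registry <- function(x, ...) {
  cat("<lipid_registry> ", length(x), " classes: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Membrane lipid classes of a registry
#'
#' Glycerophospho- and sphingolipid classes: the denominator of
#' mol%-of-membrane normalization. Neutral storage lipids (DG, TG, CE) are
#' excluded.
#'
#' @param registry a `lipid_registry`.
#' @export
membrane_classes <- function(registry) {
  names(registry)[vapply(registry, `[[`, TRUE, "membrane")]
}

# Serialization -----------------------------------------------------------

#' Write / read a class registry as YAML
#'
#' The registry ships as an editable configuration: backbone compositions
#' become molecular formula strings, grids and adducts plain lists.
#'
#' @param registry a `lipid_registry`.
#' @param path file path of the YAML document.
#' @return `read_registry` returns a `lipid_registry`.
#' @export
write_registry <- function(registry, path) {
  ser <- lapply(registry, function(d) {
    list(backbone = format_formula(d$backbone),
         chains = d$chains,
         sphingoid = d$sphingoid,
         quant_polarity = d$quant_polarity,
         quant_adduct = d$quant_adduct,
         extra_adducts = as.list(d$extra_adducts),
         membrane = d$membrane,
         lyso_partner = if (is.na(d$lyso_partner)) NULL else d$lyso_partner,
         grid = list(c_range = d$grid$c_range, c_by = d$grid$c_by,
                     db_range = d$grid$db_range,
                     oh = as.list(d$grid$oh)))
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Write / read an internal standard set as YAML
#'
#' @param standards a `standard_set` data.frame.
#' @param path YAML file path.
#' @return `read_standards` returns a `standard_set`.
#' @export
write_standards <- function(standards, path) {
  ser <- lapply(seq_len(nrow(standards)), function(k)
    list(species = standards$species[k], pmol = standards$pmol[k]))
  names(ser) <- standards$class_name
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_standards
#' @export
read_standards <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- data.frame(class_name = names(raw),
                    species = vapply(raw, `[[`, "", "species"),
                    pmol = vapply(raw, function(x) as.numeric(x$pmol), 0),
                    row.names = NULL)
  class(out) <- c("standard_set", "data.frame")
  out
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- lapply(names(raw), function(nm) {
    d <- raw[[nm]]
    bb <- if (identical(d$backbone, "") || is.null(d$backbone))
      elemental_composition() else parse_formula(d$backbone)
    .class_def(nm, bb, as.integer(d$chains), isTRUE(d$sphingoid),
               d$quant_polarity, d$quant_adduct,
               as.character(unlist(d$extra_adducts)), isTRUE(d$membrane),
               list(c_range = as.integer(unlist(d$grid$c_range)),
                    c_by = as.integer(d$grid$c_by),
                    db_range = as.integer(unlist(d$grid$db_range)),
                    oh = as.integer(unlist(d$grid$oh))),
               if (is.null(d$lyso_partner)) NA_character_ else d$lyso_partner)
  })
  names(defs) <- names(raw)
  structure(defs, class = "lipid_registry")
}
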