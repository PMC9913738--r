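test_that("sum-composition labels parse and round-trip exactly", {
  sp <- parse_sum_formula("PC(38:6)")
  expect_equal(sp$class_name, "PC")
  expect_equal(sp$carbons, 38L)
  expect_equal(sp$double_bonds, 6L)
  expect_equal(species_label(sp), "PC(38:6)")

  sm <- parse_sum_formula("SM(36:1:2)")
  expect_equal(sm$carbons, 36L)
  expect_equal(sm$double_bonds, 1L)
  expect_equal(sm$hydroxyls, 2L)
  expect_equal(species_label(sm), "SM(36:1:2)")

  # whitespace normalization
  expect_equal(species_label(parse_sum_formula(" PC( 38 : 6 ) ")), "PC(38:6)")

  # every label the registry grids emit round-trips
  reg <- default_registry()
  for (cls in names(reg)) {
    for (sp in spotlipids:::.grid_species(cls, reg)) {
      lab <- species_label(sp)
      expect_identical(species_label(parse_sum_formula(lab, reg)), lab)
    }
  }
})

test_that("malformed labels are rejected with informative errors", {
  expect_error(parse_sum_formula("XYZ(34:1)"), "unknown lipid class")
  expect_error(parse_sum_formula("PC(34:1:2)"), "two indices")
  expect_error(parse_sum_formula("SM(36:1)"), "three indices")
  expect_error(parse_sum_formula("PC(34.5:1)"), "malformed")
  expect_error(parse_sum_formula(""), "empty")
  expect_error(lipid_species("PC", 34, -1), "non-negative")
})

test_that("elemental compositions match literature formulas for all classes", {
  for (lab in names(LITERATURE_FORMULAS)) {
    comp <- composition_of(parse_sum_formula(lab))
    expect_identical(format_formula(comp), LITERATURE_FORMULAS[[lab]],
                     label = lab)
    expect_equal(monoisotopic_mass(comp),
                 oracle_mass(LITERATURE_FORMULAS[[lab]]),
                 tolerance = 1e-7, label = lab)
  }
})

test_that("composition arithmetic is element-wise and guards negatives", {
  pc342 <- composition_of("PC(34:2)")
  pc365 <- composition_of("PC(36:5)")
  # +2 C gives +4 H, +3 DB removes 6 H: net +C2 -H2
  diff <- elemental_composition(C = 2)
  expect_true((pc365 + elemental_composition(H = 2)) == (pc342 + diff))
  # one-chain removal: PC(32:0) - LPC(16:0) = 16:0 acyl minus water
  acyl_minus_water <- composition_of("PC(32:0)") - composition_of("LPC(16:0)")
  palmitic <- parse_formula("C16H32O2")
  water <- elemental_composition(H = 2, O = 1)
  expect_true((acyl_minus_water + water) == palmitic)
  # subtraction below zero is a chemistry error
  expect_error(composition_of("LPC(16:0)") - composition_of("PC(32:0)"),
               "negative")
  # mass additivity over random composition pairs
  set.seed(11)
  for (i in 1:25) {
    a <- elemental_composition(C = sample(1:60, 1), H = sample(1:120, 1),
                               O = sample(0:20, 1), P = sample(0:2, 1))
    b <- elemental_composition(C = sample(1:60, 1), H = sample(1:120, 1),
                               N = sample(0:3, 1), S = sample(0:1, 1))
    expect_equal(monoisotopic_mass(a + b),
                 monoisotopic_mass(a) + monoisotopic_mass(b))
  }
})

test_that("adduct m/z follows the ion contract", {
  # the diagnostic isobar: sodiated PC(34:2) vs protonated PC(36:5)
  d <- adduct_mz("PC(36:5)", "[M+H]+") - adduct_mz("PC(34:2)", "[M+Na]+")
  expect_equal(round(d, 4), 0.0024)
  # protonated PC(34:2)
  expect_equal(adduct_mz("PC(34:2)", "[M+H]+"), 758.5694, tolerance = 1e-4)
  # [M+H]+ - [M-H]- = two proton masses for any species
  s <- parse_sum_formula("PE(34:1)")
  expect_equal(adduct_mz(s, "[M+H]+", check_admissible = FALSE) -
                 adduct_mz(s, "[M-H]-"),
               2 * 1.007276, tolerance = 1e-5)
  # inadmissible pairings rejected
  expect_error(adduct_mz("PE(34:1)", "[M+Na]+"), "not admissible")
})

test_that("adduct m/z agrees with the independent summation oracle", {
  reg <- default_registry()
  set.seed(7)
  adducts <- adduct_types()$adduct
  checked <- 0L
  while (checked < 50L) {
    cls <- sample(names(reg), 1)
    pool <- spotlipids:::.grid_species(cls, reg)
    sp <- pool[[sample(length(pool), 1)]]
    a <- sample(adducts, 1)
    mz <- adduct_mz(sp, a, reg, check_admissible = FALSE)
    expect_equal(mz, oracle_mz(format_formula(composition_of(sp, reg)), a),
                 tolerance = 1e-5,
                 label = paste(species_label(sp), a))
    checked <- checked + 1L
  }
})

test_that("homolog ladders step by two methylene masses", {
  reg <- default_registry()
  for (cls in names(reg)) {
    g <- reg[[cls]]$grid
    a <- reg[[cls]]$quant_adduct
    z <- abs(spotlipids:::.adduct_def(a)$charge)
    db <- g$db_range[1]
    oh <- if (reg[[cls]]$sphingoid) g$oh[1] else NULL
    s1 <- lipid_species(cls, g$c_range[1], db, oh, reg)
    s2 <- lipid_species(cls, g$c_range[1] + 2L, db, oh, reg)
    step <- (adduct_mz(s2, a, reg) - adduct_mz(s1, a, reg)) * z
    expect_equal(step, 28.0313, tolerance = 1e-4, label = cls)
  }
})

test_that("isotope envelopes follow the binomial law", {
  c42 <- parse_formula("C42H80NO8P")
  env <- isotope_distribution(c42, 3)
  r <- 0.0107 / 0.9893
  expect_equal(env$abundance[env$n13c == 0], 1)
  expect_equal(env$abundance[env$n13c == 1], 42 * r, tolerance = 1e-10)
  # A2/A0 against brute-force enumeration of two-heavy-atom placements
  expect_equal(env$abundance[env$n13c == 2], choose(42, 2) * r^2,
               tolerance = 1e-10)
  # offsets are exact isotope mass differences
  expect_equal(env$offset[env$n13c == 1], 1.0033548378)
  # no carbon, no chlorine: a single monoisotopic peak
  env0 <- isotope_distribution(elemental_composition(H = 2, O = 1), 4)
  expect_equal(nrow(env0), 1L)
  expect_equal(env0$abundance, 1)
  # chloride adducts carry the 37Cl isotopologue
  envcl <- isotope_distribution(parse_formula("C42H80NO8PCl"), 3)
  i37 <- envcl$n37cl == 1 & envcl$n13c == 0
  expect_equal(envcl$abundance[i37], 0.24229 / 0.75771, tolerance = 1e-10)
  expect_equal(envcl$offset[i37], 1.9970499)
  expect_error(isotope_distribution(elemental_composition()), "empty")
})

test_that("registry and standards round-trip through YAML", {
  reg <- default_registry()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_registry(reg, f)
  reg2 <- read_registry(f)
  expect_identical(names(reg2), names(reg))
  for (cls in names(reg)) {
    expect_true(reg2[[cls]]$backbone == reg[[cls]]$backbone)
    expect_identical(reg2[[cls]]$quant_adduct, reg[[cls]]$quant_adduct)
    expect_identical(reg2[[cls]]$grid$c_range, reg[[cls]]$grid$c_range)
  }
  # the shipped configuration equals the built-in defaults
  shipped <- read_registry(system.file("extdata", "lipid_classes.yaml",
                                       package = "spotlipids"))
  expect_identical(vapply(shipped, function(d) format_formula(d$backbone), ""),
                   vapply(reg, function(d) format_formula(d$backbone), ""))
  std <- default_standards()
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_standards(std, f2)
  expect_equal(read_standards(f2), std)
})

test_that("every class maps to one quantification polarity per the platform", {
  reg <- default_registry()
  negative <- c("PC", "PC-O", "PE", "PE-P", "PI", "PS", "PA", "PG/BMP", "CL",
                "LPC", "LPE", "LPI", "LPS", "LPG", "LCL",
                "Cer", "HexCer", "GM3", "Sulf")
  positive <- c("SM", "DG", "TG", "CE")
  for (cls in negative)
    expect_identical(reg[[cls]]$quant_polarity, "negative", label = cls)
  for (cls in positive)
    expect_identical(reg[[cls]]$quant_polarity, "positive", label = cls)
  # PC additionally observed in positive mode
  expect_true(all(c("[M+H]+", "[M+Na]+") %in% reg$PC$extra_adducts))
})
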