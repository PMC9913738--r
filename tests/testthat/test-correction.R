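test_that("type-I correction rescales by the monoisotopic envelope fraction", {
  prof <- make_profile("PE(34:1)", 10)
  std <- default_standards()[default_standards()$class_name == "PE", ]
  sim <- simulate_spot(prof, spot_spec(30000), std, noiseless_acq())
  idx <- build_candidates(default_registry(), "negative", standards = std)
  m <- isotope_correct(match_peaks(sim$negative, idx))
  pe <- m[m$species == "PE(34:1)", ]
  # corrected intensity is the full ion amount: 10 pmol/ug x 0.3 ug
  expect_equal(pe$intensity_corrected, 3, tolerance = 1e-12)
  # the raw/corrected ratio equals A0 / sum(envelope) for C39
  env <- isotope_distribution(composition_of("PE(34:1)") -
                                elemental_composition(H = 1), 3)
  expect_equal(pe$intensity / pe$intensity_corrected,
               env$abundance[1] / sum(env$abundance), tolerance = 1e-12)
  # a (hypothetical) carbon- and chlorine-free ion needs no correction
  env0 <- isotope_distribution(elemental_composition(H = 3, N = 1), 3)
  expect_equal(sum(env0$abundance), 1)
})

test_that("type-II subtraction recovers fused double-bond homologs", {
  # at reduced resolving power the A2 cluster of PC(34:3) fuses with the
  # monoisotopic peak of PC(34:2); prediction-based subtraction must
  # recover both within 1%
  reg <- default_registry()
  # contaminator comparable to the target: the fused centroid stays within
  # the mass tolerance, so the species remains identifiable and the
  # correction can recover it (a dominant contaminator would drag the
  # centroid off the candidate position entirely)
  prof <- make_profile(c("PC(34:3)", "PC(34:2)"), c(2, 8))
  acq <- noiseless_acq(resolution_at_200 = 60000)
  sim <- simulate_spot(prof, spot_spec(30000), pc_standard(), acq)
  q <- quantify_spot(sim$negative, sim$positive, standards = pc_standard(),
                     resolution_at_200 = 60000)
  truth <- sim$truth
  for (s in c("PC(34:3)", "PC(34:2)")) {
    expect_equal(q$pmol[q$species == s],
                 truth$pmol[truth$species == s],
                 tolerance = 0.01, label = s)
  }
  # switching type II off leaves the fused species overestimated
  q0 <- quantify_spot(sim$negative, sim$positive, standards = pc_standard(),
                      resolution_at_200 = 60000, type2 = FALSE)
  expect_gt(q0$pmol[q0$species == "PC(34:2)"],
            1.03 * truth$pmol[truth$species == "PC(34:2)"])
})

test_that("doubly charged cardiolipin ladders are corrected at full resolution", {
  reg <- default_registry()
  prof <- make_profile(c("CL(72:8)", "CL(72:7)"), c(2, 2))
  std <- default_standards()[default_standards()$class_name == "CL", ]
  sim <- simulate_spot(prof, spot_spec(30000), std, noiseless_acq())
  q <- quantify_spot(sim$negative, sim$positive, standards = std,
                     na_correction = FALSE)
  truth <- sim$truth
  for (s in c("CL(72:8)", "CL(72:7)"))
    expect_equal(q$pmol[q$species == s], truth$pmol[truth$species == s],
                 tolerance = 1e-6, label = s)
})

test_that("sodiation estimation: exact when noiseless, zero when absent", {
  prof <- make_lipidome(seed = 7)
  spot <- spot_spec(30000)
  sim <- simulate_spot(prof, spot, acq = noiseless_acq(f_na = 0.10))
  q <- quantify_spot(sim$negative, sim$positive)
  expect_equal(attr(q, "f_na"), 0.10, tolerance = 1e-9)
  sim0 <- simulate_spot(prof, spot, acq = noiseless_acq(f_na = 0))
  q0 <- quantify_spot(sim0$negative, sim0$positive)
  expect_equal(attr(q0, "f_na"), 0)
  # fallback with warning when no chloride reference profile exists
  empty_neg <- match_peaks(peak_list(numeric(0), numeric(0), "negative"),
                           build_candidates(default_registry(), "negative"))
  pos_idx <- build_candidates(default_registry(), "positive")
  m_pos <- isotope_correct(match_peaks(sim$positive, pos_idx))
  expect_warning(f <- estimate_sodiation(m_pos, empty_neg),
                 "fallback")
  expect_equal(as.numeric(f), 0.10)
})

test_that("sodiation estimation stays within 2 points under 5% noise", {
  prof <- make_lipidome(seed = 7)
  est <- vapply(1:8, function(s) {
    sim <- simulate_spot(prof, spot_spec(30000),
                         acq = acquisition_spec(seed = 300 + s))
    attr(quantify_spot(sim$negative, sim$positive), "f_na")
  }, 0)
  expect_true(all(est >= 0.08 & est <= 0.12))
})

test_that("sodiated-PC overlap correction recovers interfered species", {
  # PC quantified from the protonated ion: the sodiated ion of PC(34:2)
  # fuses with [PC(36:5)+H]+ and inflates the polyenoic species
  reg <- registry_pc_positive()
  # PC(38:2) is partner-free on both sides: the sodiation estimator reads
  # the clean ratio off it
  prof <- make_profile(c("PC(34:2)", "PC(36:5)", "PC(38:2)"),
                       c(20, 4, 10), reg)
  sim <- simulate_spot(prof, spot_spec(30000), pc_standard(reg),
                       noiseless_acq(f_na = 0.10), reg)
  truth <- sim$truth
  q <- quantify_spot(sim$negative, sim$positive, standards = pc_standard(reg),
                     registry = reg)
  expect_equal(q$pmol[q$species == "PC(36:5)"],
               truth$pmol[truth$species == "PC(36:5)"], tolerance = 0.02)
  expect_equal(q$pmol[q$species == "PC(34:2)"],
               truth$pmol[truth$species == "PC(34:2)"], tolerance = 1e-6)
  # skipping the correction overestimates the interfered polyenoic species
  q0 <- quantify_spot(sim$negative, sim$positive,
                      standards = pc_standard(reg), registry = reg,
                      na_correction = FALSE)
  expect_gt(q0$pmol[q0$species == "PC(36:5)"],
            1.2 * truth$pmol[truth$species == "PC(36:5)"])
  # monotonicity: correction only lowers interfered intensities and leaves
  # non-interfered species untouched
  m <- attr(q, "matches")
  m0 <- attr(q0, "matches")
  cols <- c("species", "adduct", "intensity_corrected")
  mm <- merge(as.data.frame(m)[c(cols, "na_corrected")],
              as.data.frame(m0)[cols], by = c("species", "adduct"))
  expect_true(all(mm$intensity_corrected.x <= mm$intensity_corrected.y + 1e-12))
  un <- mm[!mm$na_corrected, ]
  expect_equal(un$intensity_corrected.x, un$intensity_corrected.y,
               tolerance = 1e-12)
})

test_that("the sodiation cascade unwinds chains of interference", {
  # PC(32:0) feeds PC(34:3), which feeds PC(36:6): each sodiated ion fuses
  # with the next protonated ion; corrected values must match ground truth
  reg <- registry_pc_positive()
  prof <- make_profile(c("PC(32:0)", "PC(34:3)", "PC(36:6)", "PC(38:2)"),
                       c(30, 10, 2, 10), reg)
  sim <- simulate_spot(prof, spot_spec(30000), pc_standard(reg),
                       noiseless_acq(f_na = 0.10), reg)
  q <- quantify_spot(sim$negative, sim$positive, standards = pc_standard(reg),
                     registry = reg)
  truth <- sim$truth
  for (s in prof$species)
    expect_equal(q$pmol[q$species == s], truth$pmol[truth$species == s],
                 tolerance = 0.02, label = s)
})

test_that("negative intensities clip to zero and are flagged", {
  reg <- registry_pc_positive()
  idx <- build_candidates(reg, "positive", standards = pc_standard(reg))
  # a lone peak at the interfered position with less intensity than the
  # predicted sodiated contribution
  mz_h36 <- adduct_mz("PC(36:5)", "[M+H]+", reg)
  mz_h34 <- adduct_mz("PC(34:2)", "[M+H]+", reg)
  pk <- peak_list(c(mz_h34, mz_h36), c(100, 2), "positive")
  m <- isotope_correct(match_peaks(pk, idx), reg)
  m2 <- na_overlap_correct(m, f_na = 0.10, reg)
  r <- m2[m2$species == "PC(36:5)", ]
  expect_equal(r$intensity_corrected, 0)
  expect_true(r$clipped)
})
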