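test_that("spot wet weight reproduces the platform's printed masses", {
  expect_equal(spot_wet_weight(spot_spec(30000)), 0.3)         # 30,000 um^2
  expect_equal(spot_wet_weight(spot_spec(49e6)), 490)          # 7 mm x 7 mm
  expect_equal(spot_wet_weight(spot_spec(5000, thickness = 2)), 0.01)
  expect_error(spot_spec(30000, thickness = 0), "thickness")
  expect_error(spot_spec(-1), "area")
})

test_that("cell-equivalent counts follow the 4000 um^3 convention", {
  expect_equal(cells_equivalent(10000, 10), 25)
  expect_equal(cells_equivalent(4000, 1), 1)
  expect_equal(cells_equivalent(5000, 10), 12.5)   # "about ten cells"
  expect_error(cells_equivalent(0, 10), "positive")
})

test_that("ground-truth lipidomes are deterministic and class-structured", {
  p1 <- make_lipidome(seed = 3)
  p2 <- make_lipidome(seed = 3)
  expect_identical(p1, p2)
  p3 <- make_lipidome(seed = 4)
  expect_false(identical(p1$conc, p3$conc))
  # species bookkeeping: requested count per class (capped by the grid)
  n_cls <- table(p1$class_name)
  expect_true(all(n_cls <= 9))
  expect_gte(nrow(p1), 150)
  # membrane concentrations sum to the configured total
  reg <- default_registry()
  memb <- p1$class_name %in% membrane_classes(reg)
  expect_equal(sum(p1$conc[memb]), 15)
  expect_error(make_lipidome(class_weights = numeric(0)), "empty")
  # class weights steer expected class mol% in their direction
  w_hi <- default_class_weights(); w_hi["SM"] <- 30
  p_hi <- make_lipidome(class_weights = w_hi, seed = 5)
  p_lo <- make_lipidome(seed = 5)
  frac <- function(p, cls) sum(p$conc[p$class_name == cls]) /
    sum(p$conc[p$class_name %in% membrane_classes(reg)])
  expect_gt(frac(p_hi, "SM"), frac(p_lo, "SM"))
})

test_that("noiseless spots place every ion at its exact theoretical position", {
  prof <- make_profile(c("PE(34:1)", "SM(36:1:2)"), c(10, 5))
  std <- default_standards()
  std <- std[std$class_name %in% c("PE", "SM"), ]
  spot <- spot_spec(30000)   # 0.3 ug
  sim <- simulate_spot(prof, spot, std, noiseless_acq())
  # PE(34:1): 10 pmol/ug x 0.3 ug = 3 pmol, [M-H]- at its exact m/z with
  # monoisotopic intensity = amount x A0 share of the truncated envelope
  mz_pe <- adduct_mz("PE(34:1)", "[M-H]-")
  env <- isotope_distribution(composition_of("PE(34:1)") -
                                elemental_composition(H = 1), 3)
  i <- which.min(abs(sim$negative$mz - mz_pe))
  expect_equal(sim$negative$mz[i], mz_pe, tolerance = 1e-9)
  expect_equal(sim$negative$intensity[i],
               3 * env$abundance[1] / sum(env$abundance), tolerance = 1e-12)
  # SM appears in positive mode only
  mz_sm <- adduct_mz("SM(36:1:2)", "[M+H]+")
  expect_true(any(abs(sim$positive$mz - mz_sm) < 1e-6))
  expect_false(any(abs(sim$negative$mz - mz_sm) < 0.01))
  expect_error(simulate_spot(prof, spot, std[std$class_name == "PE", ],
                             noiseless_acq()),
               "standards missing")
})

test_that("sodiated PC ions carry the configured fraction of the protonated", {
  prof <- make_profile("PC(34:1)", 10)
  sim <- simulate_spot(prof, spot_spec(30000), pc_standard(),
                       noiseless_acq(f_na = 0.10))
  mz_h <- adduct_mz("PC(34:1)", "[M+H]+")
  mz_na <- adduct_mz("PC(34:1)", "[M+Na]+")
  ih <- sim$positive$intensity[which.min(abs(sim$positive$mz - mz_h))]
  ina <- sim$positive$intensity[which.min(abs(sim$positive$mz - mz_na))]
  expect_equal(ina / ih, 0.10, tolerance = 1e-12)
})

test_that("peak lists are deterministic, sorted and within the mass window", {
  prof <- make_lipidome(seed = 8)
  acq <- acquisition_spec(seed = 21)
  s1 <- simulate_spot(prof, spot_spec(20000), acq = acq)
  s2 <- simulate_spot(prof, spot_spec(20000), acq = acq)
  expect_identical(s1$negative, s2$negative)
  expect_identical(s1$positive, s2$positive)
  for (pk in list(s1$negative, s1$positive)) {
    expect_true(all(diff(pk$mz) > 0))
    expect_true(all(pk$intensity >= acq$noise_floor))
    expect_true(all(pk$mz >= 400 & pk$mz <= 1300))
  }
})

test_that("laser-ablation degradation conserves pmol and raises lyso + PA", {
  prof <- make_lipidome(seed = 42)
  spot <- spot_spec(30000)
  s0 <- simulate_spot(prof, spot, acq = noiseless_acq(degradation = 0))
  sd <- simulate_spot(prof, spot, acq = noiseless_acq(degradation = 0.02))
  expect_equal(sum(s0$truth$pmol), sum(sd$truth$pmol), tolerance = 1e-12)
  lyso <- c("LPC", "LPE", "LPI", "LPS", "LPG", "LCL", "PA")
  ly0 <- sum(s0$truth$pmol[s0$truth$class_name %in% lyso])
  lyd <- sum(sd$truth$pmol[sd$truth$class_name %in% lyso])
  expect_gt(lyd, ly0)
  # diacyl donors lose exactly the routed fraction (standards excluded)
  endo <- function(s) s$truth[!s$truth$species %in%
                                default_standards()$species, ]
  pc0 <- sum(endo(s0)$pmol[endo(s0)$class_name == "PC"])
  pcd <- sum(endo(sd)$pmol[endo(sd)$class_name == "PC"])
  expect_equal(pcd / pc0, 0.98, tolerance = 1e-10)
})

test_that("area series: bookkeeping, scaling and noise all behave", {
  prof <- make_lipidome(seed = 42)
  ser <- simulate_area_series(prof, acq = noiseless_acq(seed = 2))
  man <- attr(ser, "manifest")
  expect_equal(length(ser), 24L)        # 6 areas x 4 replicates
  expect_equal(sort(unique(man$area)), c(5, 10, 20, 40, 80, 160) * 1e3)
  # noiseless: total simulated amount exactly proportional to area
  std_sp <- default_standards()$species
  tot <- vapply(ser, function(s)
    sum(s$truth$pmol[!s$truth$species %in% std_sp]), 0)
  expect_equal(unname(tot / man$area),
               rep(unname(tot[1]) / man$area[1], 24), tolerance = 1e-12)
  # doubling area doubles expected intensity (noiseless construction)
  expect_equal(unname(tot[man$area == 10000][1] / tot[man$area == 5000][1]),
               2, tolerance = 1e-12)
})

test_that("region simulations tag ROIs and share profiles within regions", {
  base <- make_lipidome(seed = 1)
  profs <- list(gc = base,
                pyr = perturb_profile(base, list(SM = 1.6), seed = 2),
                ca2 = perturb_profile(base, list(SM = 0.4, Sulf = 3), seed = 3),
                mol = perturb_profile(base, list(PC = 1.3), seed = 4),
                slm = perturb_profile(base, list(PE = 1.4), seed = 5),
                rad = perturb_profile(base, list(PI = 1.5), seed = 6))
  ds <- simulate_regions(profs, replicates = 3, acq = noiseless_acq(seed = 9))
  man <- attr(ds, "manifest")
  expect_equal(length(ds), 33L)         # 11 ROIs x 3 sections
  expect_equal(length(unique(man$roi)), 11L)
  expect_equal(as.vector(table(man$region)[c("gc", "pyr", "rad")]),
               c(6L, 9L, 9L))           # 2-, 3-, 3-ROI groups x 3 sections
  # ROIs sharing a region have identical expected lipidomes up to geometry
  gc_rois <- unique(man$roi[man$region == "gc"])
  t1 <- ds[[which(man$roi == gc_rois[1])[1]]]$truth
  t2 <- ds[[which(man$roi == gc_rois[2])[1]]]$truth
  a1 <- man$area[man$roi == gc_rois[1]][1]
  a2 <- man$area[man$roi == gc_rois[2]][1]
  m <- merge(t1, t2, by = "species")
  std <- m$species %in% default_standards()$species
  expect_equal(m$pmol.x[!std] / m$pmol.y[!std],
               rep(a1 / a2, sum(!std)), tolerance = 1e-12)
  expect_error(simulate_regions(profs["gc"]), ">= 2 region profiles")
})
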