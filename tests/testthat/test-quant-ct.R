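profileFromHu <- function(hu, spacing = 1, state = "EXP_PEEP5", patient = "P") {
  n <- length(hu)
  d <- c(n, 1L, 1L)
  vol <- CTVolume(array(hu, d), spacing = spacing, patientId = patient,
                  state = state)
  aerationProfile(vol, mask(array(TRUE, d), spacing, patientId = patient,
                            state = state))
}

test_that("gas and tissue fractions follow the clamped linear HU relation", {
  fr <- voxelFractions(c(-1000, -500, 0, 80, -1200))
  expect_equal(fr$gas, c(1, 0.5, 0, 0, 1))
  expect_equal(fr$tissue, c(0, 0.5, 1, 1, 0))
  expect_true(all(fr$gas + fr$tissue == 1))
  expect_error(voxelFractions(NaN), "finite")
})

test_that("compartment classification reproduces the integer HU ranges", {
  expect_equal(as.character(classifyCompartment(c(-950, -901, -900, -501,
                                                  -500, -300, -101, -100,
                                                  0, 40, 150))),
               c("hyper", "hyper", "normal", "normal", "poorly", "poorly",
                 "poorly", "non_aerated", "non_aerated", "non_aerated",
                 "non_aerated"))
})

test_that("aeration profile weights and volumes are exact on uniform blocks", {
  # 1000 voxels of 1 mm^3 at 0 HU: 1 mL tissue = 1 g, no gas
  p0 <- profileFromHu(rep(0, 1000))
  expect_equal(lungWeight(p0), 1)
  expect_equal(gasVolume(p0), 0)
  # at -500 HU: half gas, half tissue
  p5 <- profileFromHu(rep(-500, 1000))
  expect_equal(lungWeight(p5), 0.5)
  expect_equal(gasVolume(p5), 0.5)
  expect_equal(eelv(p5), 0.5)
  # pure gas
  pg <- profileFromHu(rep(-1000, 1000))
  expect_equal(eelv(pg), 1)
  expect_equal(lungWeight(pg), 0)
  # dense voxels above +100 HU counted separately, mass conserved
  pd <- profileFromHu(c(rep(150, 10), rep(-300, 90)))
  expect_equal(pd@nVoxelsAbove100HU, 10)
  expect_equal(lungWeight(pd), sum(lungWeight(pd, aerationCompartments)))
  expect_error(aerationProfile(
    CTVolume(array(0, c(4, 4, 4))), mask(array(FALSE, c(4, 4, 4)))),
    "empty")
})

test_that("recruitment arithmetic and sign conventions are exact", {
  # wNon voxels of 0 HU (non-aerated, tissue fraction 1) plus poorly aerated
  # voxels at -500 HU (tissue fraction 0.5) prescribe W_non and W_total
  # exactly, in units of one 1-mm^3 voxel weight
  mk <- function(wNon, wTotal, state) {
    profileFromHu(c(rep(0, wNon), rep(-500, 2 * (wTotal - wNon))),
                  state = state)
  }
  p5 <- mk(600, 1000, "EXP_PEEP5")
  p15 <- mk(500, 1000, "EXP_PEEP15")
  expect_equal(recruitmentPeep(p5, p15), 10, tolerance = 1e-6)
  expect_equal(recruitmentPeep(p5, p5), 0)
  expect_equal(recruitmentPeep(p5, p15), -recruitmentPeep(p15, p5))
  p5b <- mk(500, 1000, "EXP_PEEP5"); p15b <- mk(530, 1000, "EXP_PEEP15")
  expect_equal(recruitmentPeep(p5b, p15b), -3, tolerance = 1e-6)
  # peep5 denominator variant
  expect_equal(recruitmentPeep(mk(600, 1050, "EXP_PEEP5"),
                               mk(500, 950, "EXP_PEEP15"),
                               denominator = "peep5"),
               100 * (600 - 500) / 1050, tolerance = 1e-6)

  pe <- mk(550, 1000, "EXP_PEEPclin"); pi <- mk(508, 1000, "INSP_PEEPclin")
  expect_equal(tidalRecruitment(pe, pi), 4.2, tolerance = 1e-6)
  pe2 <- mk(400, 1000, "EXP_PEEPclin"); pi2 <- mk(420, 1000, "INSP_PEEPclin")
  expect_equal(tidalRecruitment(pe2, pi2), -2, tolerance = 1e-6)
})

test_that("tidal hyperinflation standardizes hyper-compartment gas to PBW", {
  pe <- profileFromHu(rep(-950, 1000), state = "EXP_PEEPclin")
  pi <- profileFromHu(rep(-950, 1000), state = "INSP_PEEPclin")
  expect_equal(tidalHyperinflation(pe, pi, 70), 0)
  # -1000 HU voxels are pure gas: 42000 and 70000 1-mm^3 voxels give hyper
  # gas volumes of 42 and 70 mL, hence (70 - 42) / 70 = 0.4 mL/kg
  peS <- profileFromHu(rep(-1000, 42000), state = "EXP_PEEPclin")
  piS <- profileFromHu(rep(-1000, 70000), state = "INSP_PEEPclin")
  expect_equal(tidalHyperinflation(peS, piS, 70), 0.4, tolerance = 1e-12)
  expect_error(tidalHyperinflation(pe, pi, 0), "positive")
})

parameterColumnsForTest <- function() c(
  "recruitment_peep_5_15_pct", "tidal_recruitment_pct",
  "tidal_hyperinflation_ml_kg", "eelv_peep5_ml", "eelv_peep15_ml",
  "nonaerated_peep5_pct", "weight_peep5_g")

test_that("per-patient parameter assembly flags absent states as NA", {
  spec <- phantomSpec(gridShape = c(24, 24, 20), seed = 3)
  profiles <- lapply(setNames(ctStates, ctStates), function(s) {
    ph <- generatePhantom(spec, s)
    aerationProfile(ph$volume, ph$mask)
  })
  full <- patientParameters(profiles, pbw = 70)
  expect_true(all(is.finite(unlist(full[parameterColumnsForTest()]))))
  partial <- patientParameters(profiles[c("EXP_PEEP5", "EXP_PEEP15")],
                               pbw = 70)
  expect_true(is.na(partial$tidal_recruitment_pct))
  expect_true(is.na(partial$tidal_hyperinflation_ml_kg))
  expect_false(is.na(partial$recruitment_peep_5_15_pct))
  bad <- profiles
  bad$EXP_PEEP5@patientId <- "someone_else"
  expect_error(patientParameters(bad, pbw = 70), "different patients")
})

test_that("profiles conserve mass and volume and are translation invariant", {
  set.seed(11)
  for (i in 1:5) {
    d <- c(14, 12, 10)
    hu <- array(runif(prod(d), -1100, 200), d)
    sel <- array(runif(prod(d)) < 0.5, d)
    if (!any(sel)) next
    vol <- CTVolume(hu, spacing = c(0.8, 1, 1.3))
    msk <- mask(sel, c(0.8, 1, 1.3))
    p <- aerationProfile(vol, msk)
    expect_equal(lungWeight(p), sum(lungWeight(p, aerationCompartments)),
                 tolerance = 1e-9)
    expect_equal(gasVolume(p) + tissueVolume(p),
                 p@nVoxels * voxelVolume(p), tolerance = 1e-9)
    # joint integer translation (into a padded grid) leaves quantities unchanged
    sh <- array(FALSE, d + c(0, 0, 1)); hs <- array(-1000, d + c(0, 0, 1))
    sh[, , 2:(d[3] + 1)] <- sel; hs[, , 2:(d[3] + 1)] <- hu
    p2 <- aerationProfile(CTVolume(hs, spacing = c(0.8, 1, 1.3)),
                          mask(sh, c(0.8, 1, 1.3)))
    expect_equal(lungWeight(p2, aerationCompartments),
                 lungWeight(p, aerationCompartments), tolerance = 1e-12)
    expect_equal(gasVolume(p2), gasVolume(p), tolerance = 1e-12)
  }
})

test_that("Devine predicted body weight matches hand values", {
  expect_equal(predictedBodyWeight("male", 152.4), 50)
  expect_equal(predictedBodyWeight("female", 170), 45.5 + 0.91 * 17.6)
})
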