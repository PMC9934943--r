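smallSpec <- function(...) phantomSpec(gridShape = c(28, 28, 24), ...)

test_that("phantom generation is a pure function of (spec, state)", {
  spec <- smallSpec(seed = 4)
  a <- generatePhantom(spec, "EXP_PEEP5")
  b <- generatePhantom(spec, "EXP_PEEP5")
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(voxelData(a$mask), voxelData(b$mask))
  c <- generatePhantom(smallSpec(seed = 5), "EXP_PEEP5")
  expect_false(identical(voxelData(a$volume), voxelData(c$volume)))
})

test_that("programmed compartment fractions are realized on the grid", {
  # all-normal phantom: nearly all weight classified normally aerated
  spec <- smallSpec(fractionsPeep5 = c(0, 0, 1, 0), recruitmentTruth = 0,
                    tidalRecruitmentTruth = 0, tidalHyperinflationTruth = 0)
  ph <- generatePhantom(spec, "EXP_PEEP5")
  p <- aerationProfile(ph$volume, ph$mask)
  expect_gte(lungWeight(p, "normal") / lungWeight(p), 0.99)
  # noiseless fixed-HU phantom: count fractions recovered exactly
  spec2 <- smallSpec(huMode = "fixed", huNoiseSd = 0, seed = 2)
  ph2 <- generatePhantom(spec2, "EXP_PEEP5")
  hu <- voxelData(ph2$volume)[voxelData(ph2$mask)]
  counts <- table(classifyCompartment(hu))
  expect_equal(as.numeric(counts / sum(counts)),
               unname(spec2@fractionsPeep5), tolerance = 1e-3)
})

test_that("HU values honour their compartment ranges under noise", {
  spec <- smallSpec(huNoiseSd = 40, seed = 6)
  for (st in c("EXP_PEEP5", "EXP_PEEP15")) {
    ph <- generatePhantom(spec, st)
    hu <- voxelData(ph$volume)[voxelData(ph$mask)]
    cmp <- classifyCompartment(hu)
    expect_true(all(hu >= -1000 & hu <= 100))
    expect_true(all(hu[cmp == "hyper"] <= -901))
  }
})

test_that("programmed recruitment is recovered on noiseless phantoms", {
  spec <- smallSpec(recruitmentTruth = 10, huMode = "fixed", huNoiseSd = 0)
  p5 <- generatePhantom(spec, "EXP_PEEP5")
  p15 <- generatePhantom(spec, "EXP_PEEP15")
  r <- recruitmentPeep(aerationProfile(p5$volume, p5$mask),
                       aerationProfile(p15$volume, p15$mask))
  expect_equal(r, 10, tolerance = 0.01)  # 0.1 % absolute on a 10 % truth
  expect_error(smallSpec(fractionsPeep5 = c(0.02, 0.4, 0.5, 0.08),
                         recruitmentTruth = 10),
               "exceeds the available")
})

test_that("mask perturbation honours identity, bias and degeneracy contracts", {
  spec <- smallSpec(seed = 7)
  ref <- generatePhantom(spec, "EXP_PEEP5")$mask
  ident <- perturbMask(ref, observerModel(0, 0, 8, "OBS1_RUN2"), seed = 1)
  expect_identical(voxelData(ident), voxelData(ref))
  expect_equal(dice(ref, ident), 1)
  dil <- perturbMask(ref, observerModel(0, 1, 8, "OBS2"), seed = 1)
  expect_true(all(voxelData(dil)[voxelData(ref)]))
  expect_gt(sum(voxelData(dil)), sum(voxelData(ref)))
  ero <- perturbMask(ref, observerModel(0, -1, 8, "OBS2"), seed = 1)
  expect_true(all(voxelData(ref)[voxelData(ero)]))
  expect_lt(sum(voxelData(ero)), sum(voxelData(ref)))
  expect_error(perturbMask(ref, observerModel(0, -100, 8, "OBS2")),
               "degenerate output")
  expect_error(perturbMask(mask(array(FALSE, c(4, 4, 4))),
                           observerModel(1, 0, 8, "OBS2")), "empty")
})

test_that("realized surface disagreement increases with the jitter setting", {
  spec <- phantomSpec(seed = 9)
  ref <- generatePhantom(spec, "EXP_PEEP5")$mask
  med <- vapply(c(0.5, 1.0, 1.6), function(j) {
    om <- observerModel(j, 0, 8, "OBS2")
    median(vapply(1:6, function(s) assd(ref, perturbMask(ref, om, seed = s)),
                  numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  # jitter 1 mm lands near its target on a lung-sized mask
  om1 <- observerModel(1, 0, 8, "OBS2")
  a1 <- median(vapply(1:20, function(s)
    assd(ref, perturbMask(ref, om1, seed = s)), numeric(1)))
  expect_gte(a1, 0.7)
  expect_lte(a1, 1.3)
})

test_that("study generation counts volumes and masks and honours missingness", {
  obs <- defaultObserverModels()
  st <- generateStudy(nPatients = 2, observers = obs, seed = 1,
                      gridShape = c(24, 24, 20))
  expect_equal(length(st@volumes), 2 * 4)
  expect_equal(length(st@masks), 2 * 4 * (1 + length(obs)))
  expect_s4_class(studyMask(st, "P01", "EXP_PEEP5", "ML"), "SegmentationMask")
  expect_equal(nrow(studyTruth(st)), 2)
  miss <- data.frame(patient_id = "P01",
                     state = c("EXP_PEEPclin", "INSP_PEEPclin"))
  st2 <- generateStudy(nPatients = 2, observers = obs, seed = 1,
                       gridShape = c(24, 24, 20), missing = miss)
  expect_equal(length(st2@volumes), 6)
  expect_null(studyVolume(st2, "P01", "EXP_PEEPclin"))
  st3 <- generateStudy(nPatients = 2, observers = obs, seed = 1,
                       gridShape = c(24, 24, 20))
  expect_identical(voxelData(studyVolume(st, "P02", "EXP_PEEP15")),
                   voxelData(studyVolume(st3, "P02", "EXP_PEEP15")))
  expect_error(generateStudy(nPatients = 1, observers = list()), "observer")
})

test_that("streaming simulation matches the in-memory study path", {
  obs <- defaultObserverModels()[1:2]
  stream <- simulateMeasurements(nPatients = 2, observers = obs, seed = 3,
                                 gridShape = c(24, 24, 20),
                                 states = c("EXP_PEEP5", "EXP_PEEP15"))
  st <- generateStudy(nPatients = 2, observers = obs, seed = 3,
                      gridShape = c(24, 24, 20),
                      states = c("EXP_PEEP5", "EXP_PEEP15"))
  wide <- studyParameters(st)
  cols <- c("patient_id", "observer", "recruitment_peep_5_15_pct",
            "eelv_peep5_ml", "weight_peep5_g")
  expect_equal(stream[cols], wide[cols], ignore_attr = TRUE)
  expect_equal(attr(stream, "truth")$recruitment_peep_5_15_pct,
               studyTruth(st)$recruitment_peep_5_15_pct)
})
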