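test_that("baseline profile has the configured boundary value and is monotone", {
  expect_equal(baselineProfile(0, "T1"), 1745)
  expect_gt(baselineProfile(0.9), baselineProfile(0.1))
  d <- seq(0, 1, by = 0.01)
  expect_true(all(diff(baselineProfile(d, "T1")) > 0))
  expect_true(all(diff(baselineProfile(d, "T2star")) > 0))
  ## ribbon average close to healthy-cortex scale
  expect_equal(integrate(function(x) baselineProfile(x), 0, 1)$value, 1860,
               tolerance = 1e-8)
  ## constant configuration
  expect_equal(baselineProfile(d, coeffs = c(1800, 0, 0, 0)),
               rep(1800, length(d)))
})

test_that("flat slab geometry yields a linear depth truth across the ribbon", {
  ph <- makeCorticalPhantom(c(64, 64, 32), ribbonThicknessMm = 3.5)
  gm <- tissueLabels(ph) == tissueCodes()[["GM"]]
  ## along z, depth truth increases linearly with constant step
  zProfile <- depthTruth(ph)[1, 1, ]
  zProfile <- zProfile[!is.na(zProfile)]
  expect_equal(length(unique(round(diff(zProfile), 10))), 1L)
  expect_true(all(diff(zProfile) > 0))
  ## structural invariants
  expect_true(all(!is.na(depthTruth(ph)[gm])))
  expect_true(all(is.na(depthTruth(ph)[!gm])))
  expect_true(all(tissueLabels(ph)[roiLabels(ph) != 0L] ==
                    tissueCodes()[["GM"]]))
})

test_that("ribbon thinner than 4 voxels is a geometry error", {
  expect_error(makeCorticalPhantom(c(16, 16, 16), voxelSize = 0.7,
                                   ribbonThicknessMm = 2.0),
               "geometry error")
})

test_that("patient shift raises the affected ROI uniformly, others unchanged", {
  shift <- 45
  sub <- data.frame(t1_profile_shift = shift, baseline_offset = 0)
  hc <- makeCorticalPhantom(c(32, 32, 24), ribbonThicknessMm = 3.5)
  pt <- makeCorticalPhantom(c(32, 32, 24), ribbonThicknessMm = 3.5,
                            subject = sub)
  lofc <- roiLabels(hc) %in% c(roiCode("lOFC", "left"),
                               roiCode("lOFC", "right"))
  other <- roiLabels(hc) != 0L & !lofc
  expect_equal(t1Truth(pt)[lofc], t1Truth(hc)[lofc] + shift)
  expect_equal(t1Truth(pt)[other], t1Truth(hc)[other])
  expect_equal(t2starTruth(pt), t2starTruth(hc))
})

test_that("noiseless HC slab reproduces the analytic baseline metrics", {
  ph <- makeCorticalPhantom(c(48, 48, 32), ribbonThicknessMm = 7,
                            undulationAmpMm = 0.7, undulationPeriodMm = 8)
  gm <- tissueLabels(ph) == tissueCodes()[["GM"]]
  qmap <- new("QuantMap", values = t1Truth(ph) * NA, voxelSize = voxelSize(ph),
              kind = "T1")
  ## sample the true T1 with the true depth (no estimation noise): metrics
  ## must approach the closed-form metrics of the baseline cubic
  vals <- array(NA_real_, dim(gm)); vals[gm] <- t1Truth(ph)[gm]
  qmap@values <- vals
  depth <- new("DepthField", values = depthTruth(ph),
               voxelSize = voxelSize(ph))
  mask <- roiLabels(ph) == roiCode("mOFC", "left")
  prof <- extractDepthProfile(qmap, mask, depth)
  m <- profileMetrics(prof)
  co <- baselineCoeffs("T1")
  analyticMean <- co[1] + co[2] / 2 + co[3] / 3 + co[4] / 4
  expect_equal(m@meanValue, analyticMean, tolerance = 0.01)
  expect_equal(m@auc, 10 * analyticMean, tolerance = 0.01)
  expect_equal(m@offset, co[1], tolerance = 0.02)
})

test_that("cohort generation reproduces the configured design", {
  co <- generateCohort(masterSeed = 5)
  expect_equal(nrow(co), 58L)
  expect_equal(sum(co$group == "MDD"), 48L)
  expect_equal(sum(co$group == "HC"), 10L)
  expect_true(all(co$age >= 20 & co$age <= 55))
  expect_equal(sum(is.na(co$ids_score)), 1L)
  expect_true(all(is.na(co$ids_score) | co$ids_score <= 84))
  expect_true(all(co$t1_profile_shift[co$group == "HC"] == 0))
  expect_false(any(co$on_antidepressants[co$group == "HC"]))
  ## reproducibility from the master seed
  expect_identical(co, generateCohort(masterSeed = 5))
  expect_false(identical(co, generateCohort(masterSeed = 6)))
})

test_that("null effect configuration gives identical group means", {
  eff <- effectConfig(groupShiftD = 0, severityCorr = 0)
  co <- generateCohort(nMdd = 2000, nHc = 2000, effects = eff,
                       masterSeed = 9, nIdsMissing = 0)
  expect_lt(abs(mean(co$t1_profile_shift[co$group == "MDD"])), 2)
  expect_true(all(co$t1_profile_shift[co$group == "HC"] == 0))
})

test_that("large-sample calibration hits the target effect and correlation", {
  eff <- effectConfig()
  co <- generateCohort(nMdd = 10000, nHc = 10000, effects = eff,
                       masterSeed = 11, nIdsMissing = 0)
  met <- co$baseline_offset + co$t1_profile_shift
  mdd <- co$group == "MDD"
  sPool <- sqrt(((sum(mdd) - 1) * var(met[mdd]) +
                   (sum(!mdd) - 1) * var(met[!mdd])) / (nrow(co) - 2))
  dHat <- (mean(met[mdd]) - mean(met[!mdd])) / sPool
  expect_lt(abs(dHat - 0.6), 0.05)
  expect_lt(abs(cor(co$t1_profile_shift[mdd], co$ids_score[mdd]) - 0.27),
            0.03)
})

test_that("rendered volumes are seed-deterministic and invert to truth", {
  ph <- makeCorticalPhantom(c(24, 24, 20), ribbonThicknessMm = 3.5,
                            undulationAmpMm = 1, undulationPeriodMm = 8)
  params <- acquisitionParams()
  a <- renderSubjectImages(ph, params, noiseSd = 0.01, seed = 123)
  b <- renderSubjectImages(ph, params, noiseSd = 0.01, seed = 123)
  expect_identical(a$uni, b$uni)
  expect_identical(a$echoes, b$echoes)
  c2 <- renderSubjectImages(ph, params, noiseSd = 0.01, seed = 124)
  expect_false(identical(a$uni, c2$uni))

  ## zero noise: estimated maps equal truth in GM
  z <- renderSubjectImages(ph, params, noiseSd = 0)
  lut <- buildT1Lookup(params)
  t1map <- estimateT1Map(z$uni, lut, voxelSize(ph))
  gm <- tissueLabels(ph) == tissueCodes()[["GM"]]
  expect_lt(max(abs(mapValues(t1map)[gm] - t1Truth(ph)[gm])), 1.0)
  t2map <- estimateT2starMap(z$echoes, params@tes, voxelSize(ph))
  expect_lt(max(abs(mapValues(t2map)[gm] - t2starTruth(ph)[gm])), 1e-6)
})

test_that("voxelwise T1 error under 1% channel noise stays below 40 ms RMSE in GM", {
  ph <- makeCorticalPhantom(c(64, 64, 32), ribbonThicknessMm = 3.5,
                            undulationAmpMm = 1.4)
  params <- acquisitionParams()
  img <- renderSubjectImages(ph, params, noiseSd = 0.01, seed = 2024)
  lut <- buildT1Lookup(params)
  uni <- pmin(pmax(img$uni, -0.5), 0.5)
  t1map <- estimateT1Map(uni, lut, voxelSize(ph))
  gm <- tissueLabels(ph) == tissueCodes()[["GM"]]
  err <- mapValues(t1map)[gm] - t1Truth(ph)[gm]
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 40)
  expect_lt(mean(is.na(err)), 0.01)
})

test_that("profile-tier simulation is deterministic and shift-consistent", {
  co <- generateCohort(nMdd = 6, nHc = 4, masterSeed = 3)
  eff <- effectConfig()
  p1 <- simulateProfileCohort(co, eff, seed = 5)
  p2 <- simulateProfileCohort(co, eff, seed = 5)
  expect_identical(p1, p2)

  ## noiseless profiles equal baseline + offset + shift exactly
  p0 <- simulateProfileCohort(co, eff, rois = c("lOFC", "S1"),
                              profileNoiseSd = 0, seed = 5)
  r <- p0[p0$subject_id == co$subject_id[1] & p0$roi == "lOFC" &
            p0$hemisphere == "left", ]
  expect_equal(r$value,
               baselineProfile(r$depth) + co$baseline_offset[1] +
                 co$t1_profile_shift[1], tolerance = 1e-9)
  rS1 <- p0[p0$subject_id == co$subject_id[1] & p0$roi == "S1" &
              p0$hemisphere == "left", ]
  expect_equal(rS1$value,
               baselineProfile(rS1$depth) + co$baseline_offset[1],
               tolerance = 1e-9)
})
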