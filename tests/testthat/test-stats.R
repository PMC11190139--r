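## Small fabricated metrics/cohort tables for inference tests.
makeRecords <- function(values, group, age, sex, roi = "lOFC",
                        contrast = "T1", metric = "mean") {
  n <- length(values)
  ids <- sprintf("s%02d", seq_len(n))
  list(
    metrics = data.frame(subject_id = ids, roi = roi,
                         hemisphere = "averaged", contrast = contrast,
                         metric = metric, value = values,
                         stringsAsFactors = FALSE),
    cohort = data.frame(subject_id = ids, group = group, age = age,
                        sex = sex, stringsAsFactors = FALSE))
  }

test_that("ANCOVA matches the partitioned-regression oracle on a toy dataset", {
  values <- c(1900, 1850, 1940, 1790, 1820, 1760, 1880, 1750)
  group <- c("MDD", "MDD", "MDD", "MDD", "HC", "HC", "HC", "HC")
  age <- c(35, 41, 29, 50, 38, 44, 31, 47)
  sex <- c("F", "M", "F", "M", "F", "M", "F", "M")
  rec <- makeRecords(values, group, age, sex)
  res <- ancovaGroupTest(rec$metrics, rec$cohort)
  oracle <- ancovaPartitionedOracle(values, group, age,
                                    as.numeric(sex == "M"))
  expect_equal(res$statistic, oracle$F, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$df2, oracle$df2)
})

test_that("ANCOVA denominator df is N - 4 in the 48/10 design", {
  co <- generateCohort(masterSeed = 2)
  prof <- simulateProfileCohort(co, rois = "lOFC", seed = 3)
  met <- computeMetricsTable(prof)
  res <- ancovaGroupTest(met, co)
  expect_equal(res$df2, 54L)
  expect_equal(res$n, 58L)
  expect_true(res$ci_lo < res$ci_hi)
})

test_that("identical metric values with balanced covariates give F = 0, p = 1", {
  rec <- makeRecords(rep(1800, 10), rep(c("MDD", "HC"), each = 5),
                     age = rep(40, 10), sex = rep(c("F", "M"), 5))
  res <- ancovaGroupTest(rec$metrics, rec$cohort)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("ANCOVA F is invariant to affine rescaling of metric and age", {
  set.seed(13)
  n <- 30
  rec <- makeRecords(1800 + rnorm(n, 0, 60),
                     sample(rep(c("MDD", "HC"), c(20, 10))),
                     age = runif(n, 20, 55),
                     sex = sample(c("F", "M"), n, replace = TRUE))
  r0 <- ancovaGroupTest(rec$metrics, rec$cohort)
  rec$metrics$value <- 3 * rec$metrics$value - 500
  rec$cohort$age <- rec$cohort$age / 10 + 2
  r1 <- ancovaGroupTest(rec$metrics, rec$cohort)
  expect_equal(r1$statistic, r0$statistic, tolerance = 1e-9)
  expect_equal(r1$p, r0$p, tolerance = 1e-9)
})

test_that("single-sex samples and tiny groups are design errors", {
  rec <- makeRecords(rnorm(8, 1800, 50), rep(c("MDD", "HC"), each = 4),
                     age = 30:37, sex = rep("F", 8))
  expect_error(ancovaGroupTest(rec$metrics, rec$cohort), "design error")
  rec2 <- makeRecords(rnorm(4, 1800, 50), c("MDD", "MDD", "MDD", "HC"),
                      age = 30:33, sex = c("F", "M", "F", "M"))
  expect_error(ancovaGroupTest(rec2$metrics, rec2$cohort), "3 subjects")
})

test_that("Kendall tau equals the O(n^2) pair-count oracle on tied data", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- sample(1:8, n, replace = TRUE) # heavy ties
    y <- x + sample(-3:3, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    res <- kendallCorrelation(x, y, nBoot = 10)
    expect_equal(res$tau, kendallPairCountOracle(x, y), tolerance = 1e-12)
  }
})

test_that("Kendall correlation handles edge cases per contract", {
  expect_equal(kendallCorrelation(1:8, 2 * (1:8), nBoot = 10)$tau, 1)
  expect_error(kendallCorrelation(1:3, 3:1), "at least 5")
  expect_error(kendallCorrelation(rep(1, 6), 1:6), "all tied")
  ## pairwise-complete handling
  x <- c(1, 2, 3, 4, 5, NA, 7)
  y <- c(2, 1, 4, 3, 6, 5, NA)
  expect_equal(kendallCorrelation(x, y, nBoot = 10)$n, 5L)
  ## bootstrap CI is seeded and contains the estimate
  r1 <- kendallCorrelation(rnorm(20), rnorm(20), seed = 4)
  r2 <- kendallCorrelation(rnorm(20), rnorm(20), seed = 4)
  set.seed(77)
  x <- rnorm(30); y <- x + rnorm(30)
  ci <- kendallCorrelation(x, y, seed = 8)
  expect_true(ci$ci_lo <= ci$tau && ci$tau <= ci$ci_hi)
})

test_that("lateralization test is null for mirrored data and detects asymmetry", {
  co <- generateCohort(masterSeed = 17)
  prof <- simulateProfileCohort(co, rois = c("lOFC", "S1"),
                                contrasts = c("T1", "T2star"), seed = 18)
  met <- computeMetricsTable(prof, averageHemis = FALSE)

  ## mirrored: copy left onto right -> t = 0, p = 1 everywhere
  mirrored <- met
  lv <- mirrored$hemisphere == "left"
  key <- paste(mirrored$subject_id, mirrored$roi, mirrored$contrast,
               mirrored$metric)
  mirrored$value[!lv] <- mirrored$value[lv][match(key[!lv], key[lv])]
  resM <- lateralizationTest(mirrored)
  expect_true(all(resM$statistic == 0))
  expect_true(all(resM$p == 1))

  ## simulated +30 ms left-only effect is detected at n = 58
  lat <- met
  sel <- lat$hemisphere == "left" & lat$contrast == "T1" &
    lat$metric == "mean"
  lat$value[sel] <- lat$value[sel] + 30
  resL <- lateralizationTest(lat)
  expect_lt(resL$p[resL$roi == "lOFC" & resL$contrast == "T1"], 0.05)

  ## symmetric synthetic cohort: no spurious asymmetry
  res0 <- lateralizationTest(met)
  expect_true(all(res0$p > 0.001))
})

test_that("within-patient analyses are gated on case-control significance", {
  co <- generateCohort(masterSeed = 23)
  prof <- simulateProfileCohort(co, rois = c("lOFC", "S1"), seed = 24)
  met <- computeMetricsTable(prof)
  stage1 <- do.call(rbind, lapply(c("lOFC", "S1"), function(r)
    ancovaGroupTest(met, co, roi = r)))

  ## artificial null gate -> empty table
  gateNull <- stage1; gateNull$p <- 0.99
  empty <- withinPatientAnalyses(met, co, gateNull, nBoot = 20)
  expect_equal(nrow(empty), 0L)

  ## forced gate -> severity/trauma correlations and med/anxiety contrasts
  gateAll <- stage1; gateAll$p[gateAll$roi == "lOFC"] <- 0.001
  out <- withinPatientAnalyses(met, co, gateAll, nBoot = 50)
  expect_true(all(out$roi == "lOFC"))
  expect_setequal(unique(out$term),
                  c("ids_score", "ctq_score", "on_antidepressants",
                    "comorbid_anxiety"))
  ## IDS correlations use the 47 patients with recorded scores
  expect_true(all(out$n[out$term == "ids_score"] == 47L))
})

test_that("severity correlation recovery is calibrated across replicates", {
  ## population tau implied by the generating mechanism, via large-sample
  ## Monte Carlo (metric = baseline offset + shift + profile noise)
  eff <- effectConfig()
  big <- generateCohort(nMdd = 20000, nHc = 2, effects = eff,
                        masterSeed = 31, nIdsMissing = 0)
  mdd <- big$group == "MDD"
  metBig <- big$baseline_offset[mdd] + big$t1_profile_shift[mdd] +
    rnorm(sum(mdd), 0, 15 / sqrt(10))
  tauTruth <- cor(metBig, big$ids_score[mdd], method = "kendall")

  hits <- 0L; taus <- numeric(40)
  for (r in 1:40) {
    co <- generateCohort(masterSeed = 100 + r, effects = eff)
    prof <- simulateProfileCohort(co, eff, rois = "lOFC", seed = 200 + r)
    met <- computeMetricsTable(prof)
    pat <- co[co$group == "MDD", ]
    df <- merge(met[met$metric == "mean", c("subject_id", "value")], pat,
                by = "subject_id")
    kc <- kendallCorrelation(df$ids_score, df$value, nBoot = 200,
                             seed = 300 + r)
    taus[r] <- kc$tau
    if (kc$ci_lo <= tauTruth && tauTruth <= kc$ci_hi) hits <- hits + 1L
  }
  expect_gte(hits, 36L) # ~90% coverage of the implied population tau
  expect_gt(mean(taus), 0) # effect direction recovered on average
})
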