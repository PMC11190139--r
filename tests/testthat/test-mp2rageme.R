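test_that("analytic steady state matches the event-driven Bloch oracle", {
  p <- acquisitionParams()
  for (t1 in c(800, 1200, 1800, 2500)) {
    a <- simulateMp2rageSignals(t1, p)
    b <- blochOracle(t1, p)
    expect_lt(abs(a$s1 - b[["s1"]]) / abs(b[["s1"]]), 1e-3)
    expect_lt(abs(a$s2 - b[["s2"]]) / abs(b[["s2"]]), 1e-3)
  }
})

test_that("no inversion in a time-symmetric cycle gives identical readouts", {
  ## eff = 0 removes the inversion; with equal blocks and the pre-block gaps
  ## equal (tb = tc + ta) both readouts see the same periodic state
  p <- acquisitionParams(ti1 = 100, ti2 = 300, trSeq = 400, trGre1 = 10,
                         trGre2 = 10, fa1 = 5, fa2 = 5, tes = c(3, 10),
                         nExc = 8L, invEff = 0)
  s <- simulateMp2rageSignals(c(900, 1500, 2400), p)
  expect_equal(s$s1, s$s2, tolerance = 1e-12)
  expect_equal(uniContrast(s$s1, s$s2), rep(0.5, 3), tolerance = 1e-12)
})

test_that("very long T1 with perfect inversion is still inverted at TI1", {
  s <- simulateMp2rageSignals(1e7, acquisitionParams(invEff = 1))
  expect_lt(s$s1, 0)
})

test_that("non-physical parameters are rejected", {
  expect_error(acquisitionParams(ti1 = 4000), "ti1 < ti2")
  expect_error(acquisitionParams(tes = c(5, 3)), "strictly increasing")
  expect_error(acquisitionParams(invEff = 1.2), "0, 1")
  expect_error(acquisitionParams(ti1 = 300), "before the inversion")
})

test_that("UNI contrast obeys its closed form and scaling invariance", {
  expect_identical(uniContrast(1, 1), 0.5)
  expect_identical(uniContrast(-1, 1), -0.5)
  expect_identical(uniContrast(0, 1), 0)
  expect_error(uniContrast(0, 0), "undefined")
  s1 <- c(-0.3, 0.02, 0.4); s2 <- c(0.5, 0.07, 0.1)
  expect_equal(uniContrast(s1 * 17, s2 * 17), uniContrast(s1, s2))
  expect_true(all(abs(uniContrast(s1, s2)) <= 0.5))
})

test_that("lookup table is strictly monotone and inverts exactly on nodes", {
  p <- acquisitionParams()
  lut <- buildT1Lookup(p, 500, 5000, 1)
  idx <- t1Grid(lut) >= validRange(lut)[1] & t1Grid(lut) <= validRange(lut)[2]
  du <- diff(uniGrid(lut)[idx])
  expect_true(all(du > 0) || all(du < 0))
  expect_true(validRange(lut)[1] <= 1500 && validRange(lut)[2] >= 2500)

  ## round trip on grid nodes inside the branch
  nodes <- seq(600, 4800, by = 300)
  sig <- simulateMp2rageSignals(nodes, p)
  uni <- uniContrast(sig$s1, sig$s2)
  rec <- mapValues(estimateT1Map(array(uni, c(length(uni), 1, 1)), lut))
  expect_equal(as.vector(rec), nodes, tolerance = 1e-12)

  expect_error(buildT1Lookup(p, 1000, 1500, 600), "resolution")
})

test_that("T1 estimation flags out-of-branch UNI values as missing", {
  lut <- buildT1Lookup(acquisitionParams(), 500, 5000, 1)
  expect_gt(0.49, max(range(uniGrid(lut)))) # 0.49 is outside the table
  vol <- array(c(0.49, 0.1), c(2, 1, 1))
  m <- estimateT1Map(vol, lut)
  expect_true(is.na(mapValues(m)[1, 1, 1]))
  expect_false(is.na(mapValues(m)[2, 1, 1]))
  expect_error(estimateT1Map(array(0.7, c(1, 1, 1)), lut), "0.5")
})

test_that("noisy T1 recovery is accurate at the median", {
  p <- acquisitionParams()
  lut <- buildT1Lookup(p, 500, 5000, 1)
  t1True <- 1900
  s <- simulateMp2rageSignals(t1True, p)
  nVox <- 1000
  set.seed(42)
  amp <- 0.01 * sqrt(s$s1^2 + s$s2^2)
  s1 <- s$s1 + rnorm(nVox, 0, amp)
  s2 <- s$s2 + rnorm(nVox, 0, amp)
  uni <- uniContrast(s1, s2)
  uni <- pmin(pmax(uni, -0.5), 0.5)
  rec <- mapValues(estimateT1Map(array(uni, c(nVox, 1, 1)), lut))
  expect_lt(abs(median(rec, na.rm = TRUE) - t1True) / t1True, 0.02)
})

test_that("multi-echo decay follows the exponential model", {
  tes <- c(3, 11.5, 19, 28.5)
  s <- simulateMultiechoDecay(100, 28.5, tes)
  expect_equal(s[4], 100 * exp(-1), tolerance = 1e-12)
  expect_equal(simulateMultiechoDecay(5, 1e12, tes), rep(5, 4),
               tolerance = 1e-9)
})

test_that("T2* fitting is exact on noiseless decay", {
  tes <- c(3, 11.5, 19, 28.5)
  vols <- lapply(simulateMultiechoDecay(80, 25, tes),
                 function(v) array(v, c(3, 3, 2)))
  fit <- estimateT2starMap(vols, tes)
  expect_equal(unique(as.vector(mapValues(fit))), 25, tolerance = 1e-9)
})

test_that("noiseless nonlinear refinement equals the log-linear closed form", {
  tes <- c(3, 11.5, 19, 28.5)
  t2s <- c(15, 22, 30, 45)
  s0s <- c(50, 80, 120, 200)
  y <- simulateMultiechoDecay(s0s, t2s, tes)
  vols <- lapply(seq_along(tes), function(k) array(y[, k], c(4, 1, 1)))
  nl <- mapValues(estimateT2starMap(vols, tes, refine = TRUE))
  ll <- mapValues(estimateT2starMap(vols, tes, refine = FALSE))
  expect_equal(as.vector(nl), t2s, tolerance = 1e-8)
  expect_equal(as.vector(nl), as.vector(ll), tolerance = 1e-8)
})

test_that("refined fit agrees with an independent nonlinear solver on noisy voxels", {
  skip_if_not_installed("minpack.lm")
  tes <- c(3, 11.5, 19, 28.5)
  set.seed(7)
  nv <- 25
  y <- simulateMultiechoDecay(rep(100, nv), rep(28, nv), tes) +
    matrix(rnorm(nv * 4, 0, 2), nv, 4)
  keep <- rowSums(y <= 0) == 0
  y <- y[keep, ]
  vols <- lapply(seq_len(4), function(k) array(y[, k], c(nrow(y), 1, 1)))
  mine <- as.vector(mapValues(estimateT2starMap(vols, tes)))
  ref <- vapply(seq_len(nrow(y)), function(i) {
    d <- data.frame(te = tes, s = y[i, ])
    fit <- minpack.lm::nlsLM(s ~ a * exp(-te / t2), data = d,
                             start = list(a = 100, t2 = 20))
    coef(fit)[["t2"]]
  }, numeric(1))
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("noisy T2* estimation has small median error and flags bad voxels", {
  tes <- c(3, 11.5, 19, 28.5)
  set.seed(11)
  nv <- 10000
  y <- simulateMultiechoDecay(rep(100, nv), rep(30, nv), tes) +
    matrix(rnorm(nv * 4, 0, 2), nv, 4)
  vols <- lapply(seq_len(4), function(k) array(y[, k], c(100, 100, 1)))
  fit <- mapValues(estimateT2starMap(vols, tes))
  expect_lt(abs(median(fit, na.rm = TRUE) - 30) / 30, 0.03)

  ## a voxel with a non-positive echo is missing, not clamped
  y2 <- simulateMultiechoDecay(c(100, 100), c(25, 25), tes)
  y2[2, 3] <- -1
  vols2 <- lapply(seq_len(4), function(k) array(y2[, k], c(2, 1, 1)))
  f2 <- mapValues(estimateT2starMap(vols2, tes))
  expect_false(is.na(f2[1, 1, 1]))
  expect_true(is.na(f2[2, 1, 1]))

  ## increasing (non-decaying) signal is flagged
  yInc <- matrix(c(10, 20, 30, 40), 1)
  vols3 <- lapply(seq_len(4), function(k) array(yInc[, k], c(1, 1, 1)))
  expect_true(is.na(mapValues(estimateT2starMap(vols3, tes))[1, 1, 1]))
})

test_that("lookup table CSV export round-trips", {
  lut <- buildT1Lookup(acquisitionParams(), 1000, 1200, 10)
  f <- tempfile(fileext = ".csv")
  writeLookupTable(lut, f)
  tab <- read.csv(f)
  expect_identical(names(tab), c("t1_ms", "uni"))
  expect_equal(tab$t1_ms, t1Grid(lut))
  expect_equal(tab$uni, uniGrid(lut), tolerance = 1e-12)
})
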