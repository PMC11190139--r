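## Independent brute-force oracles used across the suite. These deliberately
## re-derive results by the most transparent method available (event-by-event
## simulation, exhaustive search, explicit normal equations) and never call
## the code paths they check.

## Event-driven Bloch simulation of the MP2RAGEME cycle: exact piecewise
## exponential relaxation between instantaneous pulses, iterated from thermal
## equilibrium for nRep cycles; signals read at the center excitation of each
## readout block.
blochOracle <- function(t1, p, nRep = 8L) {
  n <- p@nExc
  nc <- n %/% 2L
  ta <- p@ti1 - n * p@trGre1 / 2
  tb <- (p@ti2 - n * p@trGre2 / 2) - (p@ti1 + n * p@trGre1 / 2)
  tc <- p@trSeq - (p@ti2 + n * p@trGre2 / 2)
  relax <- function(m, t) m * exp(-t / t1) + (1 - exp(-t / t1))
  m <- 1
  s1 <- s2 <- NA_real_
  for (r in seq_len(nRep)) {
    m <- (1 - 2 * p@invEff) * m
    m <- relax(m, ta)
    for (j in seq_len(n)) {
      if (j == nc + 1L) s1 <- sin(p@fa1 * pi / 180) * m
      m <- relax(cos(p@fa1 * pi / 180) * m, p@trGre1)
    }
    m <- relax(m, tb)
    for (j in seq_len(n)) {
      if (j == nc + 1L) s2 <- sin(p@fa2 * pi / 180) * m
      m <- relax(cos(p@fa2 * pi / 180) * m, p@trGre2)
    }
    m <- relax(m, tc)
  }
  c(s1 = s1, s2 = s2)
}

## O(n^2) Kendall tau-b by explicit pair counting with tie corrections.
kendallPairCountOracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1L
      if (s < 0) disc <- disc + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

## Exhaustive nearest-voxel depth: for every GM voxel scan ALL WM and CSF
## voxels.
depthBruteForce <- function(labels, voxelSize) {
  voxelSize <- rep_len(voxelSize, 3L)
  codes <- tissueCodes()
  gmIdx <- which(labels == codes[["GM"]], arr.ind = TRUE)
  wmIdx <- which(labels == codes[["WM"]], arr.ind = TRUE)
  csfIdx <- which(labels == codes[["CSF"]], arr.ind = TRUE)
  mm <- function(idx) sweep(idx - 1, 2L, voxelSize, `*`)
  g <- mm(gmIdx); w <- mm(wmIdx); cs <- mm(csfIdx)
  out <- array(NA_real_, dim(labels))
  for (i in seq_len(nrow(g))) {
    dw <- sqrt(min(colSums((t(w) - g[i, ])^2)))
    dc <- sqrt(min(colSums((t(cs) - g[i, ])^2)))
    out[gmIdx[i, 1], gmIdx[i, 2], gmIdx[i, 3]] <- dw / (dw + dc)
  }
  out
}

## Brute-force city-block dilation: voxels within Manhattan radius r of the
## mask (the r-fold 6-connected cross dilation), intersected with GM.
dilateBruteForce <- function(roiMask, gmMask, r) {
  idx <- which(roiMask, arr.ind = TRUE)
  out <- array(FALSE, dim(roiMask))
  all3 <- as.matrix(expand.grid(i = seq_len(dim(roiMask)[1]),
                                j = seq_len(dim(roiMask)[2]),
                                k = seq_len(dim(roiMask)[3])))
  for (v in seq_len(nrow(all3))) {
    d <- min(abs(idx[, 1] - all3[v, 1]) + abs(idx[, 2] - all3[v, 2]) +
               abs(idx[, 3] - all3[v, 3]))
    if (d <= r) out[all3[v, 1], all3[v, 2], all3[v, 3]] <- TRUE
  }
  out & gmMask
}

## Explicit normal-equations cubic OLS at the 10 bin centers.
cubicNormalEquationsOracle <- function(x, y) {
  X <- cbind(1, x, x^2, x^3)
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

## Partitioned-regression ANCOVA oracle: the partial F for the group
## indicator after residualizing on the covariates, via explicit normal
## equations only.
ancovaPartitionedOracle <- function(value, group, age, sexM) {
  X0 <- cbind(1, age, sexM)
  h0 <- X0 %*% solve(t(X0) %*% X0, t(X0))
  g <- as.numeric(group == "HC")
  rG <- g - h0 %*% g
  rY <- value - h0 %*% value
  bhat <- sum(rG * rY) / sum(rG^2)
  res <- rY - bhat * rG
  n <- length(value)
  sse <- sum(res^2)
  fstat <- bhat^2 * sum(rG^2) / (sse / (n - 4))
  list(F = fstat, df2 = n - 4L,
       p = stats::pf(fstat, 1, n - 4, lower.tail = FALSE))
}

## Tiny undulated phantom shared by laminar tests.
makeTestSlab <- function(n = 16L, undulation = 0.6, thickness = 3.5) {
  makeCorticalPhantom(c(n, n, n), voxelSize = 0.7,
                      ribbonThicknessMm = thickness,
                      undulationAmpMm = undulation,
                      undulationPeriodMm = 7)
}

## DepthProfile construction shortcut for metric tests.
makeProfile <- function(values, depths = (seq_along(values) - 0.5) /
                          length(values), subjectId = "s1", roi = "lOFC",
                        hemisphere = "left", contrast = "T1",
                        nVoxels = rep(50L, length(values))) {
  new("DepthProfile", subjectId = subjectId, roi = roi,
      hemisphere = hemisphere, contrast = contrast, depths = depths,
      values = values, nVoxels = as.integer(nVoxels))
}
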