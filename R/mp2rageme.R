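#' MP2RAGEME acquisition parameters with 7T protocol defaults
#'
#' Constructor for [AcquisitionParams-class]. Defaults reproduce a 0.7 mm
#' isotropic 7T MP2RAGEME protocol: inversion times 670 / 3675.4 ms, flip
#' angles 4 / 4 degrees, GRE excitation spacings 6.2 / 31 ms, sequence TR
#' 6778 ms, four echoes at 3, 11.5, 19, 28.5 ms in the second readout, turbo
#' factor 150. The inversion efficiency of the adiabatic pulse is not a
#' protocol printout; 0.96 is a typical value and only shifts the T1 lookup
#' curve, which lookup-based estimation absorbs.
#'
#' @param ti1,ti2 inversion times (ms) at the readout-block centers.
#' @param trSeq whole-sequence repetition time (ms).
#' @param trGre1,trGre2 excitation spacing within the two GRE blocks (ms).
#' @param fa1,fa2 flip angles (degrees).
#' @param tes echo times of the second, multi-echo block (ms).
#' @param nExc excitations per block (turbo factor).
#' @param invEff inversion efficiency in [0, 1].
#' @return an [AcquisitionParams-class] object.
#' @examples
#' acquisitionParams()
#' @export
acquisitionParams <- function(ti1 = 670, ti2 = 3675.4, trSeq = 6778,
                              trGre1 = 6.2, trGre2 = 31,
                              fa1 = 4, fa2 = 4,
                              tes = c(3, 11.5, 19, 28.5),
                              nExc = 150L, invEff = 0.96) {
  new("AcquisitionParams",
      ti1 = as.numeric(ti1), ti2 = as.numeric(ti2), trSeq = as.numeric(trSeq),
      trGre1 = as.numeric(trGre1), trGre2 = as.numeric(trGre2),
      fa1 = as.numeric(fa1), fa2 = as.numeric(fa2),
      tes = as.numeric(tes), nExc = as.integer(nExc),
      invEff = as.numeric(invEff))
}

## Affine maps m -> a*m + b on the longitudinal magnetization (M0 = 1):
## free relaxation over t, and j small-flip excitations at spacing tr.
.relaxOp <- function(t, T1) {
  E <- exp(-t / T1)
  list(a = E, b = 1 - E)
}

## j pulse-relax cycles: per cycle m -> cos(fa)*E*m + (1 - E).
.blockOp <- function(j, fa, tr, T1) {
  if (j == 0L) return(list(a = rep(1, length(T1)), b = rep(0, length(T1))))
  E <- exp(-tr / T1)
  f <- cos(fa * pi / 180) * E
  a <- f^j
  b <- (1 - E) * (1 - a) / (1 - f)
  list(a = a, b = b)
}

.composeOps <- function(...) {
  ops <- list(...)
  a <- 1; b <- 0
  for (op in ops) { # applied left to right
    b <- op$a * b + op$b
    a <- op$a * a
  }
  list(a = a, b = b)
}

## Gap durations between inversion, readout blocks and cycle end, treating
## each block as spanning nExc excitations centered on its inversion time.
.sequenceGaps <- function(params) {
  half1 <- params@nExc * params@trGre1 / 2
  half2 <- params@nExc * params@trGre2 / 2
  list(
    ta = params@ti1 - half1,
    tb = (params@ti2 - half2) - (params@ti1 + half1),
    tc = params@trSeq - (params@ti2 + half2)
  )
}

#' Steady-state MP2RAGEME signal amplitudes
#'
#' Solves the periodic steady state of the longitudinal magnetization under
#' the MP2RAGEME cycle — inversion of efficiency `invEff`, free recovery,
#' `nExc` small-flip excitations per GRE block, free recovery between blocks —
#' and returns the transverse signal amplitudes excited at the centers of the
#' two readout blocks. Proton density and receive gain are common positive
#' factors that cancel in the combined contrast, so amplitudes are returned
#' with unit equilibrium magnetization.
#'
#' @param t1 longitudinal relaxation time(s), ms; vectorized.
#' @param params an [AcquisitionParams-class] object.
#' @return a list with numeric vectors `s1` and `s2` (dimensionless,
#'   signed).
#' @examples
#' s <- simulateMp2rageSignals(1500, acquisitionParams())
#' uniContrast(s$s1, s$s2)
#' @export
simulateMp2rageSignals <- function(t1, params = acquisitionParams()) {
  stopifnot(is.numeric(t1), all(is.finite(t1)), all(t1 > 0))
  validObject(params)
  g <- .sequenceGaps(params)
  n <- params@nExc
  nc <- n %/% 2L # pulses fired before the center echo of a block

  ## inversion of efficiency eff: mz -> (1 - 2*eff) * mz, the chord between
  ## identity (eff = 0, no inversion) and a perfect 180 degree flip (eff = 1)
  inv <- list(a = rep(1 - 2 * params@invEff, length(t1)),
              b = rep(0, length(t1)))
  opA <- .relaxOp(g$ta, t1)
  blk1 <- .blockOp(n, params@fa1, params@trGre1, t1)
  opB <- .relaxOp(g$tb, t1)
  blk2 <- .blockOp(n, params@fa2, params@trGre2, t1)
  opC <- .relaxOp(g$tc, t1)

  cyc <- .composeOps(inv, opA, blk1, opB, blk2, opC)
  if (any(abs(cyc$a) >= 1))
    stop("invalid parameters: steady state does not converge (|a| >= 1)")
  mss <- cyc$b / (1 - cyc$a) # longitudinal magnetization just before inversion

  pre1 <- .composeOps(inv, opA)
  m1 <- pre1$a * mss + pre1$b # before first pulse of block 1
  half1 <- .blockOp(nc, params@fa1, params@trGre1, t1)
  s1 <- sin(params@fa1 * pi / 180) * (half1$a * m1 + half1$b)

  pre2 <- .composeOps(inv, opA, blk1, opB)
  m2 <- pre2$a * mss + pre2$b
  half2 <- .blockOp(nc, params@fa2, params@trGre2, t1)
  s2 <- sin(params@fa2 * pi / 180) * (half2$a * m2 + half2$b)

  list(s1 = s1, s2 = s2)
}

#' Combined (UNI) MP2RAGE contrast
#'
#' `UNI = s1 * s2 / (s1^2 + s2^2)`, bounded in [-0.5, 0.5] and invariant to
#' any common positive scaling of the two signals, which removes proton
#' density and receive-field bias.
#'
#' @param s1,s2 signal amplitudes (signed); vectorized.
#' @return numeric vector of UNI values.
#' @export
uniContrast <- function(s1, s2) {
  stopifnot(length(s1) == length(s2))
  den <- s1^2 + s2^2
  if (any(den == 0))
    stop("undefined contrast: s1 = s2 = 0")
  s1 * s2 / den
}

#' Build a T1 lookup table for the UNI contrast
#'
#' Tabulates the steady-state UNI contrast over a T1 grid and identifies the
#' largest strictly monotone branch, preferring the branch that covers
#' typical 7T cortical T1 (1500-2500 ms). UNI -> T1 inversion is restricted
#' to that branch.
#'
#' @param params an [AcquisitionParams-class] object.
#' @param t1Min,t1Max grid bounds (ms).
#' @param step grid step (ms).
#' @return a [LookupTable-class] object.
#' @examples
#' lut <- buildT1Lookup(acquisitionParams(), step = 10)
#' validRange(lut)
#' @export
buildT1Lookup <- function(params = acquisitionParams(),
                          t1Min = 500, t1Max = 5000, step = 1) {
  stopifnot(t1Min > 0, t1Min < t1Max, step > 0)
  if (step > (t1Max - t1Min))
    stop("resolution error: grid step exceeds the requested T1 range")
  grid <- seq(t1Min, t1Max, by = step)
  sig <- simulateMp2rageSignals(grid, params)
  uni <- uniContrast(sig$s1, sig$s2)

  d <- sign(diff(uni))
  if (all(d == 0))
    stop("resolution error: UNI constant over the grid")
  runs <- rle(as.vector(d))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0
  if (!any(keep))
    stop("resolution error: no strictly monotone interval found")
  starts <- starts[keep]; ends <- ends[keep]; lens <- runs$lengths[keep]
  ## a run over diffs [i, j] means uni is monotone on grid nodes [i, j + 1]
  lo <- grid[starts]; hi <- grid[ends + 1L]
  covers <- pmin(hi, 2500) - pmax(lo, 1500)
  best <- order(-pmin(pmax(covers, 0), 1000), -lens)[1L]
  new("LookupTable",
      t1Grid = grid, uniGrid = uni,
      validRange = c(lo[best], hi[best]), params = params)
}

#' Estimate a T1 map from a UNI volume
#'
#' Voxelwise inversion of the UNI contrast by linear interpolation on the
#' monotone branch of a lookup table. Voxels whose UNI value falls outside
#' the branch are flagged missing (`NA`), never clamped.
#'
#' @param uniVolume 3D numeric array of UNI values in [-0.5, 0.5].
#' @param lut a [LookupTable-class].
#' @param voxelSize voxel edge lengths (mm), recycled to length 3.
#' @return a [QuantMap-class] of kind `"T1"`.
#' @export
estimateT1Map <- function(uniVolume, lut, voxelSize = 0.7) {
  stopifnot(is.array(uniVolume), length(dim(uniVolume)) == 3L)
  u <- as.vector(uniVolume)
  if (any(u[!is.na(u)] < -0.5 - 1e-9 | u[!is.na(u)] > 0.5 + 1e-9))
    stop("UNI values must lie in [-0.5, 0.5]")
  idx <- t1Grid(lut) >= validRange(lut)[1] & t1Grid(lut) <= validRange(lut)[2]
  ug <- uniGrid(lut)[idx]
  tg <- t1Grid(lut)[idx]
  if (ug[1] > ug[length(ug)]) { ug <- rev(ug); tg <- rev(tg) }
  t1 <- stats::approx(ug, tg, xout = u, method = "linear",
                      yleft = NA_real_, yright = NA_real_, ties = "ordered")$y
  new("QuantMap",
      values = array(t1, dim(uniVolume)),
      voxelSize = rep_len(as.numeric(voxelSize), 3L), kind = "T1")
}

#' Monoexponential multi-echo decay
#'
#' `s_k = s0 * exp(-te_k / t2star)`, the transverse decay sampled by the
#' multi-echo readout.
#'
#' @param s0 signal amplitude(s) at echo time 0; vectorized.
#' @param t2star apparent transverse relaxation time(s), ms.
#' @param tes echo times (ms).
#' @return if `s0` is scalar, a numeric vector over echoes; otherwise a
#'   matrix with one row per element of `s0` and one column per echo.
#' @examples
#' simulateMultiechoDecay(100, 28.5, c(3, 11.5, 19, 28.5))
#' @export
simulateMultiechoDecay <- function(s0, t2star, tes = c(3, 11.5, 19, 28.5)) {
  stopifnot(all(s0 > 0), all(t2star > 0), all(tes >= 0))
  if (length(s0) == 1L && length(t2star) == 1L)
    return(s0 * exp(-tes / t2star))
  n <- max(length(s0), length(t2star))
  s0 <- rep_len(s0, n); t2star <- rep_len(t2star, n)
  s0 * exp(outer(-1 / t2star, tes))
}

## Vectorized Gauss-Newton refinement of (s0, r2star) per voxel for the
## monoexponential model, starting from the log-linear solution. 'y' is a
## voxels x echoes matrix of positive signals.
.t2starGaussNewton <- function(y, tes, s0, r2, maxIter = 50L, tol = 1e-12) {
  for (it in seq_len(maxIter)) {
    ex <- exp(outer(-r2, tes)) # n x k
    f <- s0 * ex
    r <- y - f
    ## Jacobian columns: d/ds0 = ex; d/dr2 = -s0 * te * ex
    j2 <- -f * rep(tes, each = nrow(y))
    a11 <- rowSums(ex * ex)
    a12 <- rowSums(ex * j2)
    a22 <- rowSums(j2 * j2)
    g1 <- rowSums(ex * r)
    g2 <- rowSums(j2 * r)
    det <- a11 * a22 - a12 * a12
    det[det == 0 | !is.finite(det)] <- NA_real_
    d1 <- (a22 * g1 - a12 * g2) / det
    d2 <- (a11 * g2 - a12 * g1) / det
    bad <- !is.finite(d1) | !is.finite(d2)
    d1[bad] <- 0; d2[bad] <- 0
    s0 <- s0 + d1
    r2 <- r2 + d2
    if (max(abs(d2) / pmax(abs(r2), 1e-12), abs(d1) / pmax(abs(s0), 1e-12))
        < tol) break
  }
  list(s0 = s0, r2 = r2)
}

#' Estimate a T2* map from multi-echo volumes
#'
#' Per-voxel monoexponential least-squares fit of the multi-echo decay. The
#' closed-form log-linear ordinary-least-squares solution initializes an
#' unweighted nonlinear (Gauss-Newton) refinement on the exponential model;
#' log-linear alone is biased under noise because the log transform reweights
#' the residuals. Voxels with any non-positive echo or with a non-decaying
#' fitted signal are flagged missing.
#'
#' @param echoVolumes list of 3D arrays (one per echo), or a 4D array with
#'   echoes along the 4th dimension.
#' @param tes echo times (ms); at least 3.
#' @param voxelSize voxel edge lengths (mm), recycled to length 3.
#' @param refine if `FALSE`, return the log-linear solution without
#'   nonlinear refinement.
#' @return a [QuantMap-class] of kind `"T2star"`.
#' @export
estimateT2starMap <- function(echoVolumes, tes = c(3, 11.5, 19, 28.5),
                              voxelSize = 0.7, refine = TRUE) {
  if (is.array(echoVolumes) && length(dim(echoVolumes)) == 4L)
    echoVolumes <- lapply(seq_len(dim(echoVolumes)[4]),
                          function(k) echoVolumes[, , , k, drop = TRUE])
  stopifnot(is.list(echoVolumes), length(echoVolumes) >= 3L,
            length(tes) == length(echoVolumes))
  dm <- dim(echoVolumes[[1]])
  stopifnot(length(dm) == 3L)
  y <- do.call(cbind, lapply(echoVolumes, as.vector))
  ok <- rowSums(!is.finite(y) | y <= 0) == 0L

  t2 <- rep(NA_real_, nrow(y))
  if (any(ok)) {
    ly <- log(y[ok, , drop = FALSE])
    teC <- tes - mean(tes)
    slope <- as.vector(ly %*% teC) / sum(teC^2)
    r2 <- -slope
    s0 <- exp(rowMeans(ly) + r2 * mean(tes))
    dec <- r2 > 0 & is.finite(r2) & is.finite(s0)
    if (refine && any(dec)) {
      gn <- .t2starGaussNewton(y[ok, , drop = FALSE][dec, , drop = FALSE],
                               tes, s0[dec], r2[dec])
      r2[dec] <- gn$r2
    }
    est <- ifelse(dec & r2 > 0, 1 / r2, NA_real_)
    t2[ok] <- est
  }
  new("QuantMap", values = array(t2, dm),
      voxelSize = rep_len(as.numeric(voxelSize), 3L), kind = "T2star")
}

#' Export a lookup table as a two-column CSV
#'
#' Writes `(t1_ms, uni)` rows for the full tabulated grid.
#'
#' @param lut a [LookupTable-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeLookupTable <- function(lut, file) {
  utils::write.csv(data.frame(t1_ms = t1Grid(lut), uni = uniGrid(lut)),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
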