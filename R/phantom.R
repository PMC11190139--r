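#' Synthetic effect configuration
#'
#' Constructor for [EffectConfig-class]. Defaults place a group effect of
#' pooled-SD standardized size 0.6 on the lateral orbitofrontal cortex with a
#' shift-severity correlation of 0.27, the scale of effects this toolkit is
#' designed to detect in a 48-patient / 10-control design.
#'
#' @param affectedRoi ROI carrying the simulated group effect.
#' @param groupShiftD target standardized (pooled-SD) group difference.
#' @param severityCorr target correlation between a patient's true T1 shift
#'   and IDS severity.
#' @param betweenSubjectSd SD of the true per-patient shift (ms).
#' @param noiseSd measurement noise, fraction of signal.
#' @param depthWeighted if `TRUE`, the shift grows linearly with depth
#'   (weight `2 * depth`, mean-preserving) instead of being uniform.
#' @return an [EffectConfig-class] object.
#' @export
effectConfig <- function(affectedRoi = "lOFC", groupShiftD = 0.6,
                         severityCorr = 0.27, betweenSubjectSd = 40,
                         noiseSd = 0.01, depthWeighted = FALSE) {
  new("EffectConfig",
      affectedRoi = affectedRoi, groupShiftD = as.numeric(groupShiftD),
      severityCorr = as.numeric(severityCorr),
      betweenSubjectSd = as.numeric(betweenSubjectSd),
      noiseSd = as.numeric(noiseSd), depthWeighted = isTRUE(depthWeighted))
}

#' Default cubic coefficients of the laminar baseline
#'
#' Coefficients (constant first) of the baseline quantitative profile over
#' normalized depth. The T1 baseline rises from 1745 ms at the WM/GM
#' boundary to 1995 ms at the pial surface with ribbon mean 1860 ms; T2*
#' rises from 26 to 30 ms (28 ms mid-ribbon). Both are monotone increasing
#' on [0, 1].
#'
#' @param contrast `"T1"` or `"T2star"`.
#' @return numeric(4), cubic coefficients over depth in [0, 1].
#' @export
baselineCoeffs <- function(contrast = c("T1", "T2star")) {
  switch(match.arg(contrast),
         T1 = c(1745, 170, 120, -40),
         T2star = c(26, 4, 0, 0))
}

#' Baseline laminar profile value
#'
#' Evaluates the smooth baseline profile (a cubic in normalized depth) of a
#' healthy cortical ribbon.
#'
#' @param depth normalized cortical depth in [0, 1]; vectorized.
#' @param contrast `"T1"` or `"T2star"`.
#' @param coeffs optional cubic coefficients (constant first) overriding
#'   [baselineCoeffs()]; a constant profile is `c(value, 0, 0, 0)`.
#' @return numeric vector of quantitative values (ms).
#' @examples
#' baselineProfile(c(0, 0.5, 1))
#' @export
baselineProfile <- function(depth, contrast = c("T1", "T2star"),
                            coeffs = NULL) {
  stopifnot(all(depth >= 0 & depth <= 1))
  if (is.null(coeffs)) coeffs <- baselineCoeffs(contrast)
  stopifnot(length(coeffs) == 4L)
  coeffs[1] + coeffs[2] * depth + coeffs[3] * depth^2 + coeffs[4] * depth^3
}

## Depth weight of the simulated shift: uniform, or linear-in-depth with unit
## mean so that the profile average shifts by exactly the subject's shift.
.shiftWeight <- function(depth, depthWeighted) {
  if (depthWeighted) 2 * depth else rep(1, length(depth))
}

#' Build a cortical-slab phantom with known laminar ground truth
#'
#' Constructs a WM | GM | CSF slab along the third axis, optionally with a
#' sinusoidal undulation of both tissue boundaries, assigns the four ROIs
#' (rACC, mOFC, lOFC, S1) x (left, right) as blocks of the gray-matter
#' ribbon, and fills in true T1/T2* fields: the laminar baseline plus the
#' subject's additive shift in the affected ROI, with fixed literature values
#' in WM and CSF.
#'
#' @param gridShape integer(3), voxels per axis.
#' @param voxelSize voxel edge length (mm), recycled to length 3.
#' @param ribbonThicknessMm cortical ribbon thickness (mm); must span at
#'   least 4 voxels.
#' @param subject one-row data.frame (a [generateCohort()] row) or `NULL`
#'   for a plain healthy slab. Used fields: `t1_profile_shift`,
#'   `baseline_offset` (both ms, defaulting to 0 when absent).
#' @param effects an [EffectConfig-class].
#' @param undulationAmpMm amplitude of the sinusoidal boundary undulation
#'   (mm); 0 gives flat boundaries.
#' @param undulationPeriodMm in-plane period of the undulation (mm).
#' @param wmT1,csfT1,wmT2star,csfT2star fixed tissue values outside GM (ms);
#'   defaults are literature-typical 7T values.
#' @param t1Coeffs,t2starCoeffs optional baseline cubic coefficients.
#' @return a [PhantomTruth-class] object.
#' @examples
#' ph <- makeCorticalPhantom(c(24, 24, 16))
#' table(tissueLabels(ph))
#' @export
makeCorticalPhantom <- function(gridShape = c(64, 64, 32), voxelSize = 0.7,
                                ribbonThicknessMm = 2.8, subject = NULL,
                                effects = effectConfig(),
                                undulationAmpMm = 0, undulationPeriodMm = 16,
                                wmT1 = 1200, csfT1 = 4000,
                                wmT2star = 27, csfT2star = 100,
                                t1Coeffs = NULL, t2starCoeffs = NULL) {
  gridShape <- as.integer(rep_len(gridShape, 3L))
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  if (ribbonThicknessMm / voxelSize[3] < 4)
    stop("geometry error: cortical ribbon must span at least 4 voxels")
  validObject(effects)

  shift <- 0; baseOff <- 0
  if (!is.null(subject)) {
    if (!is.null(subject$t1_profile_shift)) shift <- subject$t1_profile_shift
    if (!is.null(subject$baseline_offset)) baseOff <- subject$baseline_offset
  }

  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  ## voxel-center coordinates in mm (0-based indexing)
  xs <- (seq_len(nx) - 1) * voxelSize[1]
  ys <- (seq_len(ny) - 1) * voxelSize[2]
  zs <- (seq_len(nz) - 1) * voxelSize[3]

  ## WM/GM boundary height z0(x, y), GM/CSF at z0 + thickness; place the
  ## ribbon in the middle of the slab
  zMid <- (nz - 1) * voxelSize[3] / 2
  und <- outer(sin(2 * pi * xs / undulationPeriodMm),
               sin(2 * pi * ys / undulationPeriodMm)) * undulationAmpMm
  z0 <- zMid - ribbonThicknessMm / 2 + und # nx x ny

  zArr <- array(rep(zs, each = nx * ny), gridShape)
  z0Arr <- array(z0, gridShape)
  depthCont <- (zArr - z0Arr) / ribbonThicknessMm

  labels <- array(.TISSUE_CODES[["WM"]], gridShape)
  labels[depthCont >= 0 & depthCont < 1] <- .TISSUE_CODES[["GM"]]
  labels[depthCont >= 1] <- .TISSUE_CODES[["CSF"]]
  gm <- labels == .TISSUE_CODES[["GM"]]
  if (!any(gm) || !any(labels == .TISSUE_CODES[["WM"]]) ||
      !any(labels == .TISSUE_CODES[["CSF"]]))
    stop("geometry error: slab does not contain all three tissue classes")

  depthTruthArr <- array(NA_real_, gridShape)
  depthTruthArr[gm] <- pmin(pmax(depthCont[gm], 0), 1)

  ## ROI blocks: hemispheres split along x, the four ROIs are y-strips with a
  ## 1-voxel gap between them and from the volume edge
  roiArr <- array(0L, gridShape)
  xi <- array(rep(seq_len(nx), times = ny * nz), gridShape)
  yi <- array(rep(rep(seq_len(ny), each = nx), times = nz), gridShape)
  hemi <- ifelse(xi <= nx %/% 2, 1L, 2L)
  stripW <- (ny - 5L) %/% 4L # 4 strips + 5 gap columns
  if (stripW >= 1L) {
    for (r in seq_along(.ROI_NAMES)) {
      yLo <- 1L + r + (r - 1L) * stripW
      yHi <- yLo + stripW - 1L
      inRoi <- gm & yi >= yLo & yi <= yHi & xi != nx %/% 2 & xi != nx %/% 2 + 1L
      roiArr[inRoi] <- 10L * r + hemi[inRoi]
    }
  }

  t1 <- array(wmT1, gridShape)
  t1[labels == .TISSUE_CODES[["CSF"]]] <- csfT1
  w <- .shiftWeight(depthTruthArr[gm], effects@depthWeighted)
  affected <- roiArr[gm] %/% 10L ==
    match(effects@affectedRoi, .ROI_NAMES)
  t1[gm] <- baselineProfile(depthTruthArr[gm], "T1", t1Coeffs) + baseOff +
    shift * w * affected

  t2 <- array(wmT2star, gridShape)
  t2[labels == .TISSUE_CODES[["CSF"]]] <- csfT2star
  t2[gm] <- baselineProfile(depthTruthArr[gm], "T2star", t2starCoeffs)

  new("PhantomTruth", labels = labels, roiLabels = roiArr,
      depthTruth = depthTruthArr, t1Truth = t1, t2starTruth = t2,
      voxelSize = voxelSize)
}

#' Forward-render the acquisition of a phantom
#'
#' Per-voxel forward simulation of the MP2RAGEME acquisition over a phantom's
#' true T1/T2* fields: the two steady-state GRE signals, the combined UNI
#' volume, and the four echo magnitudes of the second readout, with noise
#' added on the channel signals. Deterministic given `seed`.
#'
#' Noise is scaled per voxel: on (s1, s2) the standard deviation is
#' `noiseSd * sqrt(s1^2 + s2^2)`, on the echoes `noiseSd * s0` where `s0` is
#' the voxel's echo amplitude at echo time zero. `"rician"` applies the noise
#' on quadrature channels and takes the magnitude (sign preserved).
#'
#' @param truth a [PhantomTruth-class].
#' @param params an [AcquisitionParams-class].
#' @param noiseSd noise fraction; 0 gives a noiseless rendering.
#' @param seed integer seed for the noise draw.
#' @param noiseModel `"gaussian"` (default) or `"rician"`.
#' @return a list with 3D arrays `s1`, `s2`, `uni`, a list `echoes` (one 3D
#'   array per echo time), `tes` and `voxelSize`.
#' @export
renderSubjectImages <- function(truth, params = acquisitionParams(),
                                noiseSd = 0.01, seed = 1L,
                                noiseModel = c("gaussian", "rician")) {
  noiseModel <- match.arg(noiseModel)
  validObject(truth)
  dm <- dim(tissueLabels(truth))
  t1 <- as.vector(t1Truth(truth))
  t2 <- as.vector(t2starTruth(truth))
  stopifnot(all(is.finite(t1)), all(is.finite(t2)))

  sig <- simulateMp2rageSignals(t1, params)
  s0 <- abs(sig$s2) # echo-train amplitude at TE = 0
  echoes <- simulateMultiechoDecay(pmax(s0, .Machine$double.eps), t2,
                                   params@tes)

  .withSeed(seed, {
    if (noiseSd > 0) {
      amp <- noiseSd * sqrt(sig$s1^2 + sig$s2^2)
      if (noiseModel == "gaussian") {
        sig$s1 <- sig$s1 + stats::rnorm(length(t1), 0, amp)
        sig$s2 <- sig$s2 + stats::rnorm(length(t1), 0, amp)
        eAmp <- noiseSd * s0
        for (k in seq_along(params@tes))
          echoes[, k] <- echoes[, k] + stats::rnorm(length(t1), 0, eAmp)
      } else {
        ric <- function(x, sd) sign(x) *
          sqrt((abs(x) + stats::rnorm(length(x), 0, sd))^2 +
                 stats::rnorm(length(x), 0, sd)^2)
        sig$s1 <- ric(sig$s1, amp)
        sig$s2 <- ric(sig$s2, amp)
        eAmp <- noiseSd * s0
        for (k in seq_along(params@tes))
          echoes[, k] <- ric(echoes[, k], eAmp)
      }
    }
  })

  list(
    s1 = array(sig$s1, dm), s2 = array(sig$s2, dm),
    uni = array(uniContrast(sig$s1, sig$s2), dm),
    echoes = lapply(seq_along(params@tes),
                    function(k) array(echoes[, k], dm)),
    tes = params@tes, voxelSize = voxelSize(truth)
  )
}
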