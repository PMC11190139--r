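#' @import methods
NULL

## Integer codes used in label volumes. Kept as plain named constants: label
## arrays stay small integer arrays rather than factors.
.TISSUE_CODES <- c(background = 0L, WM = 1L, GM = 2L, CSF = 3L)
.ROI_NAMES <- c("rACC", "mOFC", "lOFC", "S1")
.HEMI_NAMES <- c("left", "right")

#' Tissue and ROI label codes
#'
#' Integer codes used in the `labels` and `roiLabels` volumes of a
#' [PhantomTruth-class] object. Tissue volumes use
#' `background = 0, WM = 1, GM = 2, CSF = 3`. ROI volumes use
#' `10 * roi + hemisphere` with `roi` in 1..4 for rACC, mOFC, lOFC, S1 and
#' `hemisphere` 1 = left, 2 = right; 0 means no ROI.
#'
#' @return `tissueCodes()` returns a named integer vector;
#'   `roiCode()` returns the integer code for one (roi, hemisphere) pair.
#' @export
tissueCodes <- function() .TISSUE_CODES

#' @param roi one of `"rACC"`, `"mOFC"`, `"lOFC"`, `"S1"`.
#' @param hemisphere `"left"` or `"right"`.
#' @rdname tissueCodes
#' @export
roiCode <- function(roi, hemisphere) {
  r <- match(match.arg(roi, .ROI_NAMES), .ROI_NAMES)
  h <- match(match.arg(hemisphere, .HEMI_NAMES), .HEMI_NAMES)
  as.integer(10L * r + h)
}

#' MP2RAGEME acquisition parameters
#'
#' Timing and flip-angle parameters of the MP2RAGEME sequence: an adiabatic
#' inversion followed by two rapid gradient-echo (GRE) readout blocks at
#' inversion times `ti1` and `ti2`, the second block multi-echo. All times are
#' in milliseconds, flip angles in degrees.
#'
#' @slot ti1,ti2 inversion times of the two GRE blocks (ms), measured from the
#'   inversion pulse to the block centers.
#' @slot trSeq whole-sequence repetition time (ms).
#' @slot trGre1,trGre2 excitation spacing within GRE blocks 1 and 2 (ms).
#' @slot fa1,fa2 flip angles of the two blocks (degrees).
#' @slot tes echo times of the second (multi-echo) block (ms), strictly
#'   increasing.
#' @slot nExc excitations per GRE block (turbo factor).
#' @slot invEff inversion efficiency in [0, 1].
#' @seealso [acquisitionParams()] for the constructor with 7T protocol
#'   defaults.
#' @export
setClass("AcquisitionParams",
  representation(
    ti1 = "numeric", ti2 = "numeric", trSeq = "numeric",
    trGre1 = "numeric", trGre2 = "numeric",
    fa1 = "numeric", fa2 = "numeric",
    tes = "numeric", nExc = "integer", invEff = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  scalars <- c(
    ti1 = object@ti1, ti2 = object@ti2, trSeq = object@trSeq,
    trGre1 = object@trGre1, trGre2 = object@trGre2,
    fa1 = object@fa1, fa2 = object@fa2, invEff = object@invEff
  )
  if (any(lengths(list(object@ti1, object@ti2, object@trSeq, object@trGre1,
                       object@trGre2, object@fa1, object@fa2, object@invEff,
                       object@nExc)) != 1L))
    return("all timing/angle slots except 'tes' must be scalars")
  if (any(!is.finite(scalars))) msg <- c(msg, "non-finite parameter")
  if (!(object@ti1 > 0 && object@ti1 < object@ti2 && object@ti2 < object@trSeq))
    msg <- c(msg, "need 0 < ti1 < ti2 < trSeq")
  if (length(object@tes) < 1L || any(object@tes < 0) ||
      is.unsorted(object@tes, strictly = TRUE))
    msg <- c(msg, "'tes' must be non-negative and strictly increasing")
  if (!(object@fa1 > 0 && object@fa1 < 90 && object@fa2 > 0 && object@fa2 < 90))
    msg <- c(msg, "flip angles must lie in (0, 90) degrees")
  if (object@nExc < 1L) msg <- c(msg, "'nExc' must be >= 1")
  if (object@invEff < 0 || object@invEff > 1)
    msg <- c(msg, "'invEff' must lie in [0, 1]")
  if (object@trGre1 <= 0 || object@trGre2 <= 0)
    msg <- c(msg, "GRE spacings must be positive")
  ## readout blocks centered on ti1/ti2 must fit inside the cycle
  half1 <- object@nExc * object@trGre1 / 2
  half2 <- object@nExc * object@trGre2 / 2
  if (object@ti1 - half1 < 0)
    msg <- c(msg, "first readout block starts before the inversion pulse")
  if (object@ti1 + half1 > object@ti2 - half2)
    msg <- c(msg, "readout blocks overlap")
  if (object@ti2 + half2 > object@trSeq)
    msg <- c(msg, "second readout block extends past trSeq")
  if (length(msg)) msg else TRUE
})

#' T1 lookup table for the MP2RAGE uniform contrast
#'
#' Tabulates the combined (UNI) contrast of the MP2RAGEME model over a T1 grid
#' and records the largest strictly monotone sub-interval, on which the
#' UNI -> T1 inversion is well posed.
#'
#' @slot t1Grid ordered T1 values (ms).
#' @slot uniGrid corresponding UNI contrast values in [-0.5, 0.5].
#' @slot validRange length-2 numeric, T1 bounds (ms) of the monotone branch.
#' @slot params the [AcquisitionParams-class] the table was built from.
#' @seealso [buildT1Lookup()], [estimateT1Map()]
#' @export
setClass("LookupTable",
  representation(
    t1Grid = "numeric", uniGrid = "numeric",
    validRange = "numeric", params = "AcquisitionParams"
  )
)

setValidity("LookupTable", function(object) {
  msg <- character()
  if (length(object@t1Grid) != length(object@uniGrid))
    msg <- c(msg, "t1Grid and uniGrid lengths differ")
  if (is.unsorted(object@t1Grid, strictly = TRUE))
    msg <- c(msg, "t1Grid must be strictly increasing")
  if (length(object@validRange) != 2L ||
      object@validRange[1] >= object@validRange[2])
    msg <- c(msg, "validRange must be an increasing length-2 numeric")
  idx <- object@t1Grid >= object@validRange[1] &
    object@t1Grid <= object@validRange[2]
  if (sum(idx) >= 2L) {
    u <- object@uniGrid[idx]
    if (!(all(diff(u) > 0) || all(diff(u) < 0)))
      msg <- c(msg, "uniGrid not strictly monotone on validRange")
  }
  if (length(msg)) msg else TRUE
})

#' Quantitative relaxation-time map
#'
#' A 3D scalar field of fitted relaxation times (ms) on a regular voxel grid.
#' Voxels where the parameter is not estimable (out-of-range contrast,
#' non-decaying signal) are carried as `NA`, never clamped or zero-filled.
#'
#' @slot values 3D numeric array (ms); `NA` marks unestimable voxels.
#' @slot voxelSize length-3 numeric, voxel edge lengths (mm).
#' @slot kind `"T1"` or `"T2star"`.
#' @export
setClass("QuantMap",
  representation(values = "array", voxelSize = "numeric", kind = "character")
)

setValidity("QuantMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive lengths (mm)")
  if (!object@kind %in% c("T1", "T2star"))
    msg <- c(msg, "'kind' must be \"T1\" or \"T2star\"")
  v <- object@values
  if (any(v[!is.na(v)] <= 0))
    msg <- c(msg, "non-missing values must be positive")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a synthetic cortical slab
#'
#' Voxel-level ground truth of a simulated cortical slab: tissue labels, ROI
#' labels, the true normalized cortical depth (defined on gray matter only,
#' 0 at the WM/GM boundary and 1 at the GM/CSF boundary), and true T1/T2*
#' fields.
#'
#' @slot labels integer 3D array with codes from [tissueCodes()].
#' @slot roiLabels integer 3D array with codes from [roiCode()]; 0 = none.
#' @slot depthTruth numeric 3D array in [0, 1] on GM voxels, `NA` elsewhere.
#' @slot t1Truth,t2starTruth numeric 3D arrays (ms).
#' @slot voxelSize length-3 numeric (mm).
#' @export
setClass("PhantomTruth",
  representation(
    labels = "array", roiLabels = "array", depthTruth = "array",
    t1Truth = "array", t2starTruth = "array", voxelSize = "numeric"
  )
)

setValidity("PhantomTruth", function(object) {
  msg <- character()
  dm <- dim(object@labels)
  for (s in c("roiLabels", "depthTruth", "t1Truth", "t2starTruth"))
    if (!identical(dim(slot(object, s)), dm))
      msg <- c(msg, sprintf("'%s' dimensions differ from 'labels'", s))
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive lengths (mm)")
  gm <- object@labels == .TISSUE_CODES[["GM"]]
  d <- object@depthTruth
  if (any(is.na(d[gm])) || any(!is.na(d[!gm])))
    msg <- c(msg, "'depthTruth' must be defined exactly on GM voxels")
  dv <- d[gm]
  if (length(dv) && (any(dv < 0) || any(dv > 1)))
    msg <- c(msg, "'depthTruth' must lie in [0, 1]")
  if (any(object@roiLabels != 0L & !gm))
    msg <- c(msg, "ROI labels must be contained in GM")
  if (length(msg)) msg else TRUE
})

#' Normalized cortical depth field
#'
#' Per-voxel normalized cortical depth on gray matter:
#' `d = D_wm / (D_wm + D_csf)` with `D_wm`, `D_csf` the Euclidean distances
#' (mm) to the nearest white-matter and CSF voxel. 0 is the WM/GM boundary,
#' 1 the GM/CSF boundary; `NA` outside GM.
#'
#' @slot values numeric 3D array in [0, 1] on GM, `NA` elsewhere.
#' @slot voxelSize length-3 numeric (mm).
#' @seealso [computeDepthField()]
#' @export
setClass("DepthField",
  representation(values = "array", voxelSize = "numeric")
)

setValidity("DepthField", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  v <- object@values[!is.na(object@values)]
  if (length(v) && (any(v < 0) || any(v > 1)))
    msg <- c(msg, "depth values must lie in [0, 1]")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive lengths (mm)")
  if (length(msg)) msg else TRUE
})

#' A 10-depth quantitative profile
#'
#' Mean quantitative values sampled at equal-width cortical depth bins for one
#' (subject, ROI, hemisphere, contrast). The canonical profile has exactly 10
#' values, at bin centers (i - 0.5)/10; bins backed by too few voxels are
#' `NA`.
#'
#' @slot subjectId character.
#' @slot roi one of rACC, mOFC, lOFC, S1.
#' @slot hemisphere `"left"`, `"right"` or `"averaged"`.
#' @slot contrast `"T1"` or `"T2star"`.
#' @slot depths bin-center depth coordinates in [0, 1].
#' @slot values per-bin mean values (ms), `NA` where undersampled.
#' @slot nVoxels per-bin voxel counts.
#' @seealso [extractDepthProfile()], [averageHemispheres()]
#' @export
setClass("DepthProfile",
  representation(
    subjectId = "character", roi = "character", hemisphere = "character",
    contrast = "character", depths = "numeric", values = "numeric",
    nVoxels = "integer"
  )
)

setValidity("DepthProfile", function(object) {
  msg <- character()
  n <- length(object@depths)
  if (length(object@values) != n || length(object@nVoxels) != n)
    msg <- c(msg, "'depths', 'values', 'nVoxels' lengths differ")
  if (any(object@depths < 0) || any(object@depths > 1))
    msg <- c(msg, "'depths' must lie in [0, 1]")
  if (is.unsorted(object@depths, strictly = TRUE))
    msg <- c(msg, "'depths' must be strictly increasing")
  if (!object@roi %in% .ROI_NAMES)
    msg <- c(msg, "unknown 'roi'")
  if (!object@hemisphere %in% c(.HEMI_NAMES, "averaged"))
    msg <- c(msg, "unknown 'hemisphere'")
  if (!object@contrast %in% c("T1", "T2star"))
    msg <- c(msg, "'contrast' must be \"T1\" or \"T2star\"")
  if (length(msg)) msg else TRUE
})

#' Scalar summaries of a depth profile
#'
#' The three parsimonious metrics reducing a 10-depth profile: the global mean
#' across depths, the area under a 3rd-order polynomial fit (spanning 10
#' depth-index units, so AUC of a flat profile c equals 10 c), and the offset,
#' i.e. the fitted value at depth 0 (the WM/GM transitional zone).
#'
#' @slot meanValue arithmetic mean of the non-missing depth values (ms).
#' @slot auc `10 * integral of p(x) over [0,1]` of the fitted cubic `p`.
#' @slot offset `p(0)` (ms).
#' @slot coeffs cubic coefficients, constant first.
#' @seealso [profileMetrics()]
#' @export
setClass("ProfileMetrics",
  representation(
    meanValue = "numeric", auc = "numeric", offset = "numeric",
    coeffs = "numeric"
  )
)

setValidity("ProfileMetrics", function(object) {
  if (length(object@coeffs) != 4L)
    return("'coeffs' must have 4 elements (constant first)")
  TRUE
})

#' Synthetic effect configuration
#'
#' Parameters of the simulated disease effect: which ROI carries it, the
#' target standardized (pooled-SD) group difference on T1 metrics, the target
#' correlation between a patient's true T1 shift and symptom severity, the
#' between-patient SD of the true shift, and the measurement noise level.
#'
#' @slot affectedRoi ROI carrying the group effect (default lOFC).
#' @slot groupShiftD target pooled-SD standardized group difference.
#' @slot severityCorr target correlation of the true shift with IDS severity,
#'   |rho| < 1.
#' @slot betweenSubjectSd SD of the true per-patient shift (ms), > 0.
#' @slot noiseSd measurement noise as a fraction of signal.
#' @slot depthWeighted if `TRUE` the shift grows linearly with depth
#'   (mean preserved) instead of being uniform across depths.
#' @seealso [effectConfig()], [generateCohort()]
#' @export
setClass("EffectConfig",
  representation(
    affectedRoi = "character", groupShiftD = "numeric",
    severityCorr = "numeric", betweenSubjectSd = "numeric",
    noiseSd = "numeric", depthWeighted = "logical"
  )
)

setValidity("EffectConfig", function(object) {
  msg <- character()
  if (!object@affectedRoi %in% .ROI_NAMES) msg <- c(msg, "unknown 'affectedRoi'")
  if (abs(object@severityCorr) >= 1) msg <- c(msg, "|severityCorr| must be < 1")
  if (object@betweenSubjectSd <= 0) msg <- c(msg, "'betweenSubjectSd' must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (length(msg)) msg else TRUE
})
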