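## 6-connected binary dilation by one voxel (cross structuring element).
.dilate6 <- function(mask) {
  out <- mask
  dm <- dim(mask)
  n <- length(dm)
  for (ax in seq_len(n)) {
    idx <- rep(list(quote(expr = )), n)
    lo <- idx; hi <- idx
    lo[[ax]] <- seq_len(dm[ax] - 1L)
    hi[[ax]] <- seq_len(dm[ax] - 1L) + 1L
    sel <- function(m, i) do.call(`[`, c(list(m), i, list(drop = FALSE)))
    shifted <- array(FALSE, dm)
    shifted <- do.call(`[<-`, c(list(shifted), hi, list(sel(mask, lo))))
    out <- out | shifted
    shifted <- array(FALSE, dm)
    shifted <- do.call(`[<-`, c(list(shifted), lo, list(sel(mask, hi))))
    out <- out | shifted
  }
  out
}

## Boundary voxels of 'mask': mask voxels with at least one 6-neighbor
## outside the mask (includes voxels on the array edge).
.maskBoundary <- function(mask) {
  dm <- dim(mask)
  interior <- array(TRUE, dm)
  for (ax in seq_len(3L)) {
    idx <- rep(list(quote(expr = )), 3L)
    first <- idx; first[[ax]] <- 1L
    last <- idx; last[[ax]] <- dm[ax]
    interior <- do.call(`[<-`, c(list(interior), first, list(FALSE)))
    interior <- do.call(`[<-`, c(list(interior), last, list(FALSE)))
  }
  shrunk <- mask & interior
  for (ax in seq_len(3L)) {
    idx <- rep(list(quote(expr = )), 3L)
    lo <- idx; hi <- idx
    lo[[ax]] <- seq_len(dm[ax] - 1L)
    hi[[ax]] <- seq_len(dm[ax] - 1L) + 1L
    sel <- function(m, i) do.call(`[`, c(list(m), i, list(drop = FALSE)))
    s1 <- array(FALSE, dm)
    s1 <- do.call(`[<-`, c(list(s1), hi, list(sel(mask, lo))))
    s2 <- array(FALSE, dm)
    s2 <- do.call(`[<-`, c(list(s2), lo, list(sel(mask, hi))))
    shrunk <- shrunk & s1 & s2
  }
  mask & !shrunk
}

## Minimum Euclidean distance (mm) from each row of 'from' (n x 3, mm) to the
## point set 'to' (m x 3, mm), chunked so the cross-distance matrix stays
## small.
.minDistance <- function(from, to, chunk = 1024L) {
  m2 <- rowSums(to^2)
  out <- numeric(nrow(from))
  i <- 1L
  while (i <= nrow(from)) {
    j <- min(i + chunk - 1L, nrow(from))
    f <- from[i:j, , drop = FALSE]
    d2 <- outer(rowSums(f^2), m2, `+`) - 2 * f %*% t(to)
    out[i:j] <- sqrt(pmax(apply(d2, 1L, min), 0))
    i <- j + 1L
  }
  out
}

.voxelCoordsMm <- function(idx, voxelSize) {
  ## 0-based voxel indices scaled to mm
  sweep(idx - 1, 2L, voxelSize, `*`)
}

#' Compute a normalized cortical depth field
#'
#' For every gray-matter voxel, the normalized depth
#' `d = D_wm / (D_wm + D_csf)` where `D_wm` and `D_csf` are Euclidean
#' distances (mm, voxel centers) to the nearest white-matter and CSF voxel.
#' This distance-ratio depth is 0 at the WM/GM boundary and 1 at the GM/CSF
#' boundary. Only boundary voxels of the WM and CSF regions are searched;
#' the nearest member of a 6-connected region to an outside point always
#' lies on its boundary, so the restriction is exact.
#'
#' @param labels integer 3D array with codes from [tissueCodes()].
#' @param voxelSize voxel edge lengths (mm), recycled to length 3.
#' @return a [DepthField-class] object.
#' @examples
#' ph <- makeCorticalPhantom(c(16, 16, 16))
#' df <- computeDepthField(tissueLabels(ph), voxelSize(ph))
#' @export
computeDepthField <- function(labels, voxelSize = 0.7) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  wm <- labels == .TISSUE_CODES[["WM"]]
  gm <- labels == .TISSUE_CODES[["GM"]]
  csf <- labels == .TISSUE_CODES[["CSF"]]
  if (!any(wm) || !any(gm) || !any(csf))
    stop("labels must contain nonempty WM, GM and CSF")

  gmIdx <- which(gm, arr.ind = TRUE)
  wmIdx <- which(.maskBoundary(wm), arr.ind = TRUE)
  csfIdx <- which(.maskBoundary(csf), arr.ind = TRUE)

  gmMm <- .voxelCoordsMm(gmIdx, voxelSize)
  dWm <- .minDistance(gmMm, .voxelCoordsMm(wmIdx, voxelSize))
  dCsf <- .minDistance(gmMm, .voxelCoordsMm(csfIdx, voxelSize))
  tot <- dWm + dCsf
  if (any(tot == 0))
    stop("geometry error: GM voxel coincides with both boundaries")

  vals <- array(NA_real_, dim(labels))
  vals[gm] <- dWm / tot
  new("DepthField", values = vals, voxelSize = voxelSize)
}

#' Refine an atlas ROI mask against a gray-matter segmentation
#'
#' Morphological dilation of the ROI label (6-connected cross, one voxel per
#' step, `dilationVoxels` steps) followed by voxelwise intersection with the
#' gray-matter mask. Dilation compensates for atlas masks that undershoot
#' the superficial ribbon; the GM intersection removes any growth outside
#' cortex.
#'
#' @param roiMask logical 3D array (or coercible) marking the ROI.
#' @param gmMask logical 3D array marking gray matter.
#' @param dilationVoxels dilation radius in voxels, 1-3.
#' @return logical 3D array, the refined mask.
#' @export
refineRoiMask <- function(roiMask, gmMask, dilationVoxels = 2L) {
  stopifnot(identical(dim(roiMask), dim(gmMask)))
  dilationVoxels <- as.integer(dilationVoxels)
  if (!dilationVoxels %in% 1:3)
    stop("'dilationVoxels' must be 1, 2 or 3")
  m <- array(as.logical(roiMask), dim(roiMask))
  for (i in seq_len(dilationVoxels)) m <- .dilate6(m)
  out <- m & array(as.logical(gmMask), dim(gmMask))
  if (!any(out))
    stop("empty-ROI error: refined mask contains no voxels")
  out
}

#' Extract a 10-depth quantitative profile
#'
#' Partitions normalized depth [0, 1] into `nDepths` equal-width bins
#' (half-open `[lo, hi)`, last bin closed) with centers `(i - 0.5)/nDepths`,
#' and averages the non-missing map values over the mask voxels falling in
#' each bin. Bins backed by fewer than `minVoxels` voxels are reported
#' missing; a profile with more than `maxMissingBins` missing bins is
#' rejected.
#'
#' @param qmap a [QuantMap-class].
#' @param mask logical 3D array, voxels to sample (must lie within GM, i.e.
#'   within the depth field's domain).
#' @param depth a [DepthField-class] on the same grid.
#' @param nDepths number of depth bins (default 10).
#' @param minVoxels minimum voxels per trusted bin.
#' @param maxMissingBins missing-bin tolerance before rejection.
#' @param subjectId,roi,hemisphere profile identity metadata.
#' @return a [DepthProfile-class] with exactly `nDepths` values.
#' @export
extractDepthProfile <- function(qmap, mask, depth, nDepths = 10L,
                                minVoxels = 10L, maxMissingBins = 2L,
                                subjectId = "subject", roi = "lOFC",
                                hemisphere = "left") {
  stopifnot(identical(dim(mapValues(qmap)), dim(mask)),
            identical(dim(mapValues(qmap)), dim(mapValues(depth))))
  nDepths <- as.integer(nDepths)
  mask <- array(as.logical(mask), dim(mask))
  d <- mapValues(depth)[mask]
  if (any(is.na(d)))
    stop("mask extends outside the depth field's gray-matter domain")
  v <- mapValues(qmap)[mask]

  bin <- pmin(floor(d * nDepths) + 1L, nDepths) # d = 1 closes the last bin
  vals <- rep(NA_real_, nDepths)
  cnt <- integer(nDepths)
  for (i in seq_len(nDepths)) {
    vi <- v[bin == i & !is.na(v)]
    cnt[i] <- length(vi)
    if (cnt[i] >= minVoxels) vals[i] <- mean(vi)
  }
  if (sum(is.na(vals)) > maxMissingBins)
    stop(sprintf("profile-quality error: %d of %d depth bins missing",
                 sum(is.na(vals)), nDepths))
  new("DepthProfile",
      subjectId = as.character(subjectId), roi = roi,
      hemisphere = hemisphere, contrast = mapKind(qmap),
      depths = (seq_len(nDepths) - 0.5) / nDepths,
      values = vals, nVoxels = cnt)
}

#' Average left and right depth profiles
#'
#' Depthwise arithmetic mean of matching left/right profiles of one subject,
#' ROI and contrast; voxel counts are summed. A depth missing on either side
#' is missing in the average.
#'
#' @param left,right [DepthProfile-class] objects of the two hemispheres.
#' @return a [DepthProfile-class] with `hemisphere = "averaged"`.
#' @export
averageHemispheres <- function(left, right) {
  if (left@subjectId != right@subjectId || left@roi != right@roi ||
      left@contrast != right@contrast)
    stop("contract error: profiles differ in subject, ROI or contrast")
  if (!identical(left@depths, right@depths))
    stop("contract error: depth grids differ")
  new("DepthProfile",
      subjectId = left@subjectId, roi = left@roi, hemisphere = "averaged",
      contrast = left@contrast, depths = left@depths,
      values = (left@values + right@values) / 2,
      nVoxels = left@nVoxels + right@nVoxels)
}
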