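#' Read and write quantitative maps as NIfTI-1
#'
#' Volumes are stored as NIfTI-1 with the voxel size in `pixdim`; world
#' orientation beyond voxel size is not interpreted. Missing voxels are
#' stored as NaN and restored to `NA` on read.
#'
#' @param map a [QuantMap-class].
#' @param file path to a `.nii` or `.nii.gz` file.
#' @return `writeQuantMap` returns the path invisibly; `readQuantMap`
#'   returns a [QuantMap-class].
#' @export
writeQuantMap <- function(map, file) {
  .writeVolume(mapValues(map), voxelSize(map), file)
  invisible(file)
}

#' @param kind `"T1"` or `"T2star"`, the stored quantity.
#' @rdname writeQuantMap
#' @export
readQuantMap <- function(file, kind = c("T1", "T2star")) {
  img <- RNifti::readNifti(file)
  v <- array(as.numeric(img), dim(img))
  v[is.nan(v)] <- NA_real_
  new("QuantMap", values = v,
      voxelSize = RNifti::pixdim(img)[seq_len(3)], kind = match.arg(kind))
}

.writeVolume <- function(values, voxelSize, file) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- rep_len(voxelSize, 3L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Export a phantom's volumes as NIfTI files
#'
#' Writes `labels.nii.gz`, `roi_labels.nii.gz`, `depth_truth.nii.gz`,
#' `t1_truth.nii.gz` and `t2star_truth.nii.gz` into a directory.
#'
#' @param truth a [PhantomTruth-class].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writePhantom <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- voxelSize(truth)
  .writeVolume(tissueLabels(truth), vs, file.path(dir, "labels.nii.gz"))
  .writeVolume(roiLabels(truth), vs, file.path(dir, "roi_labels.nii.gz"))
  .writeVolume(depthTruth(truth), vs, file.path(dir, "depth_truth.nii.gz"))
  .writeVolume(t1Truth(truth), vs, file.path(dir, "t1_truth.nii.gz"))
  .writeVolume(t2starTruth(truth), vs,
               file.path(dir, "t2star_truth.nii.gz"))
  invisible(dir)
}
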