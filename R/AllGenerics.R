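#' Accessors for laminarq S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a laminarq S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))

#' @rdname accessors
#' @export
setGeneric("t1Grid", function(x) standardGeneric("t1Grid"))

#' @rdname accessors
#' @export
setGeneric("uniGrid", function(x) standardGeneric("uniGrid"))

#' @rdname accessors
#' @export
setGeneric("validRange", function(x) standardGeneric("validRange"))

#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname accessors
#' @export
setGeneric("depthTruth", function(x) standardGeneric("depthTruth"))

#' @rdname accessors
#' @export
setGeneric("t1Truth", function(x) standardGeneric("t1Truth"))

#' @rdname accessors
#' @export
setGeneric("t2starTruth", function(x) standardGeneric("t2starTruth"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("profileDepths", function(x) standardGeneric("profileDepths"))

#' @rdname accessors
#' @export
setGeneric("voxelCounts", function(x) standardGeneric("voxelCounts"))

#' @rdname accessors
#' @export
setMethod("mapValues", "QuantMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("mapValues", "DepthField", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("voxelSize", "QuantMap", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "DepthField", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "PhantomTruth", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("mapKind", "QuantMap", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("t1Grid", "LookupTable", function(x) x@t1Grid)

#' @rdname accessors
#' @export
setMethod("uniGrid", "LookupTable", function(x) x@uniGrid)

#' @rdname accessors
#' @export
setMethod("validRange", "LookupTable", function(x) x@validRange)

#' @rdname accessors
#' @export
setMethod("tissueLabels", "PhantomTruth", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("roiLabels", "PhantomTruth", function(x) x@roiLabels)

#' @rdname accessors
#' @export
setMethod("depthTruth", "PhantomTruth", function(x) x@depthTruth)

#' @rdname accessors
#' @export
setMethod("t1Truth", "PhantomTruth", function(x) x@t1Truth)

#' @rdname accessors
#' @export
setMethod("t2starTruth", "PhantomTruth", function(x) x@t2starTruth)

#' @rdname accessors
#' @export
setMethod("profileValues", "DepthProfile", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("profileDepths", "DepthProfile", function(x) x@depths)

#' @rdname accessors
#' @export
setMethod("voxelCounts", "DepthProfile", function(x) x@nVoxels)

setMethod("show", "AcquisitionParams", function(object) {
  cat("MP2RAGEME acquisition parameters\n")
  cat(sprintf("  TI1/TI2: %.1f / %.1f ms   TRseq: %.1f ms\n",
              object@ti1, object@ti2, object@trSeq))
  cat(sprintf("  TRgre:  %.1f / %.1f ms   FA: %g / %g deg   turbo: %d\n",
              object@trGre1, object@trGre2, object@fa1, object@fa2,
              object@nExc))
  cat(sprintf("  TEs: %s ms   inversion efficiency: %.2f\n",
              paste(object@tes, collapse = ", "), object@invEff))
  invisible(object)
})

setMethod("show", "LookupTable", function(object) {
  cat(sprintf("T1 lookup table: %d nodes, %.0f-%.0f ms (step %g ms)\n",
              length(object@t1Grid), min(object@t1Grid), max(object@t1Grid),
              object@t1Grid[2] - object@t1Grid[1]))
  cat(sprintf("  monotone branch: %.0f-%.0f ms, UNI %.4f..%.4f\n",
              object@validRange[1], object@validRange[2],
              object@uniGrid[match(object@validRange[1], object@t1Grid)],
              object@uniGrid[match(object@validRange[2], object@t1Grid)]))
  invisible(object)
})

setMethod("show", "QuantMap", function(object) {
  v <- object@values
  cat(sprintf("%s map: %s voxels at %s mm, %d missing\n", object@kind,
              paste(dim(v), collapse = "x"),
              paste(signif(object@voxelSize, 3), collapse = "x"),
              sum(is.na(v))))
  fin <- v[!is.na(v)]
  if (length(fin))
    cat(sprintf("  range %.1f-%.1f ms, median %.1f ms\n",
                min(fin), max(fin), stats::median(fin)))
  invisible(object)
})

setMethod("show", "PhantomTruth", function(object) {
  lab <- object@labels
  cat(sprintf("Cortical slab phantom: %s voxels at %s mm\n",
              paste(dim(lab), collapse = "x"),
              paste(signif(object@voxelSize, 3), collapse = "x")))
  for (nm in names(.TISSUE_CODES))
    cat(sprintf("  %s: %d voxels\n", nm, sum(lab == .TISSUE_CODES[[nm]])))
  cat(sprintf("  ROI voxels: %d\n", sum(object@roiLabels != 0L)))
  invisible(object)
})

setMethod("show", "DepthField", function(object) {
  cat(sprintf("Cortical depth field: %s voxels, %d GM voxels\n",
              paste(dim(object@values), collapse = "x"),
              sum(!is.na(object@values))))
  invisible(object)
})

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("%s depth profile | subject %s | %s (%s), %d depths\n",
              object@contrast, object@subjectId, object@roi,
              object@hemisphere, length(object@depths)))
  cat("  values:", paste(sprintf("%.1f", object@values), collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "ProfileMetrics", function(object) {
  cat(sprintf("Profile metrics: mean %.2f | AUC %.2f | offset %.2f\n",
              object@meanValue, object@auc, object@offset))
  invisible(object)
})

setMethod("show", "EffectConfig", function(object) {
  cat(sprintf(
    "Effect config: ROI %s, d = %.2f, severity rho = %.2f, shift SD %.0f ms\n",
    object@affectedRoi, object@groupShiftD, object@severityCorr,
    object@betweenSubjectSd))
  invisible(object)
})
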