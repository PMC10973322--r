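## Generics, accessors and show methods.

#' Access the HU grid of a CTVolume
#' @param x A [CTVolume-class].
#' @return The 3D HU array.
#' @export
setGeneric("huData", function(x) standardGeneric("huData"))

#' @rdname huData
#' @export
setMethod("huData", "CTVolume", function(x) x@hu)

#' Access voxel spacing (mm)
#' @param x A [CTVolume-class] or [MuscleMask-class].
#' @return Numeric length-3 spacing in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "MuscleMask", function(x) x@spacing)

#' Access the binary grid of a MuscleMask
#' @param x A [MuscleMask-class].
#' @return The 3D logical array.
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname maskData
#' @export
setMethod("maskData", "MuscleMask", function(x) x@mask)

#' Access the slice interval of a MuscleMask
#' @param x A [MuscleMask-class].
#' @return Integer length-2 inclusive slice interval.
#' @export
setGeneric("zRange", function(x) standardGeneric("zRange"))

#' @rdname zRange
#' @export
setMethod("zRange", "MuscleMask", function(x) x@zRange)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@hu)
  cat("CTVolume:", paste(d, collapse = " x "), "voxels,",
      paste(object@spacing, collapse = " x "), "mm\n")
  cat("  HU range: [", min(object@hu), ",", max(object@hu), "]\n")
  cat("  z axis:", if (object@kneeToAnkle) "knee -> ankle" else
      "unknown orientation", "\n")
})

setMethod("show", "MuscleMask", function(object) {
  d <- dim(object@mask)
  cat("MuscleMask:", paste(d, collapse = " x "), "voxels,",
      sum(object@mask), "in mask, z range [",
      object@zRange[1], ",", object@zRange[2], "]\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@gridShape, collapse = " x "),
      "voxels at", paste(object@spacing, collapse = " x "), "mm\n")
  m <- object@tissueParams$muscle_mild
  s <- object@tissueParams$muscle_severe
  cat(sprintf("  muscle HU: mild %.1f (SD %.1f), severe %.1f (SD %.1f)\n",
              m[["mean"]], m[["sd"]], s[["mean"]], s[["sd"]]))
  cat(sprintf("  imf %.3f, distal %.1f HU (%s), noise SD %.1f, seed %d\n",
              object@imfFraction, object@distalGradient,
              object@distalProfile, object@noiseSD, object@seed))
})

setMethod("show", "SegmentationParams", function(object) {
  cat(sprintf(
    "SegmentationParams: HU window [%g, %g], min component %d, bone >= %g\n",
    object@huLow, object@huHigh, object@minComponentVoxels, object@boneHuMin))
})

setMethod("show", "DiscretizationParams", function(object) {
  cat(sprintf("DiscretizationParams: bin width %g HU, distance %d, %s\n",
              object@binWidth, object@distance, object@mode))
})
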