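#' Construct a CTVolume
#'
#' @param hu 3D numeric array of Hounsfield units.
#' @param spacing Voxel spacing in mm, length 3.
#' @param kneeToAnkle Logical; slice 1 is the knee end (the package-wide
#'   convention).
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- ctVolume(array(50, c(8, 8, 8)))
#' @export
ctVolume <- function(hu, spacing = c(1, 1, 1), kneeToAnkle = TRUE) {
  new("CTVolume", hu = hu, spacing = as.numeric(spacing),
      kneeToAnkle = kneeToAnkle)
}

#' Construct a MuscleMask
#'
#' @param mask 3D logical array.
#' @param spacing Voxel spacing in mm, length 3.
#' @param zRange Inclusive slice interval; defaults to the full z extent.
#' @return A [MuscleMask-class] object.
#' @export
muscleMask <- function(mask, spacing = c(1, 1, 1), zRange = NULL) {
  mask <- array(as.logical(mask), dim(mask))
  if (is.null(zRange)) zRange <- c(1L, dim(mask)[3])
  new("MuscleMask", mask = mask, spacing = as.numeric(spacing),
      zRange = as.integer(zRange))
}

#' Default tissue HU parameters of the lower-leg phantom
#'
#' Muscle parameters follow the reported group summaries (mild 44.6/16.0
#' HU, severe 39.5/16.7 HU); the remaining tissues use textbook CT
#' attenuation values.  Marrow (30 HU) and veins (90 HU) deliberately sit
#' inside the muscle threshold window so that segmentation must remove
#' them structurally, while contrast-filled arteries (300 HU) and
#' subcutaneous fat (-100 HU) fall outside it.
#'
#' @return Named list of `c(mean =, sd =)` HU pairs.
#' @export
defaultTissueParams <- function() {
  list(
    muscle_mild       = c(mean = 44.6,  sd = 16.0),
    muscle_severe     = c(mean = 39.5,  sd = 16.7),
    subcutaneous_fat  = c(mean = -100,  sd = 10),
    intramuscular_fat = c(mean = -80,   sd = 10),
    cortical_bone     = c(mean = 1000,  sd = 50),
    marrow            = c(mean = 30,    sd = 10),
    artery_contrast   = c(mean = 300,   sd = 30),
    vein              = c(mean = 90,    sd = 10),
    air               = c(mean = -1000, sd = 0)
  )
}

#' Construct a PhantomSpec
#'
#' Defaults define the study conditions the rest of the package assumes:
#' a 64 x 64 x 60 grid at 3 x 3 x 5 mm spacing (a lower leg covered by
#' 60 axial CTA slices), the group muscle HU parameters above, 2%
#' intramuscular-fat speckle, a -4 HU severe-group distal offset with a
#' profile peaking at 70% of the knee-to-ankle axis, and between-subject
#' variability of 4 HU (mean) / 0.6 HU (SD) applied at cohort level.
#'
#' @param gridShape Voxels per axis.
#' @param spacing Voxel spacing in mm.
#' @param tissueParams See [defaultTissueParams()].
#' @param imfFraction Fraction of muscle voxels replaced by
#'   intramuscular fat.
#' @param distalGradient Peak HU offset applied to severe subjects'
#'   muscle along the knee-to-ankle axis.
#' @param distalProfile `"peaked"` or `"linear"`.
#' @param noiseSD Additive HU noise SD on the whole grid.
#' @param subjectMuSD,subjectSigmaSD Between-subject SDs of the muscle
#'   mean and SD, used by [generateCohort()].
#' @param seed Integer master seed.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(seed = 1L)
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 60L),
                        spacing = c(3, 3, 5),
                        tissueParams = defaultTissueParams(),
                        imfFraction = 0.02,
                        distalGradient = -4,
                        distalProfile = "peaked",
                        noiseSD = 0,
                        subjectMuSD = 4,
                        subjectSigmaSD = 0.6,
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), tissueParams = tissueParams,
      imfFraction = imfFraction, distalGradient = distalGradient,
      distalProfile = distalProfile, noiseSD = noiseSD,
      subjectMuSD = subjectMuSD, subjectSigmaSD = subjectSigmaSD,
      seed = as.integer(seed))
}

#' Construct SegmentationParams
#'
#' @param huLow,huHigh Inclusive HU window (defaults -10 and 100).
#' @param minComponentVoxels Minimum 3D component size kept (default 27,
#'   i.e. a 3 x 3 x 3 noise speckle).
#' @param boneHuMin Cortical-bone detector threshold (default 300 HU).
#' @return A [SegmentationParams-class] object.
#' @export
segmentationParams <- function(huLow = -10, huHigh = 100,
                               minComponentVoxels = 27L, boneHuMin = 300) {
  new("SegmentationParams", huLow = huLow, huHigh = huHigh,
      minComponentVoxels = as.integer(minComponentVoxels),
      boneHuMin = boneHuMin)
}

#' Construct DiscretizationParams
#'
#' @param binWidth Fixed HU bin width, anchored at the ROI minimum.
#' @param distance Neighbour distance in voxels.
#' @param mode `"3d"` or `"2d"`.
#' @return A [DiscretizationParams-class] object.
#' @export
discretizationParams <- function(binWidth = 5, distance = 1L, mode = "3d") {
  new("DiscretizationParams", binWidth = binWidth,
      distance = as.integer(distance), mode = mode)
}
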