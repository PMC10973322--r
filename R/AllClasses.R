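## S4 containers for the imaging side of the analysis.

#' CTVolume: a 3D CT attenuation grid
#'
#' Holds a three-dimensional grid of Hounsfield units (HU) together with
#' the voxel spacing.  The z axis runs knee to ankle (increasing slice
#' index) throughout the package; `kneeToAnkle` records that the volume
#' obeys the convention and is asserted at load time.
#'
#' @slot hu 3D numeric/integer array of Hounsfield units.
#' @slot spacing Numeric length-3, voxel spacing in mm (x, y, z).
#' @slot kneeToAnkle Logical flag; slice 1 is the most proximal (knee).
#'
#' @seealso [ctVolume()] for the user-facing constructor, [huData()],
#'   [voxelSpacing()].
#' @export
setClass("CTVolume",
  representation(hu = "array", spacing = "numeric", kneeToAnkle = "logical"),
  prototype(spacing = c(1, 1, 1), kneeToAnkle = TRUE)
)

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@hu)) != 3L)
    msg <- c(msg, "'hu' must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive values (mm)")
  rng <- suppressWarnings(range(object@hu))
  if (is.finite(rng[1]) && (rng[1] < -1024 || rng[2] > 3071))
    msg <- c(msg, "HU values must lie within [-1024, 3071]")
  if (length(object@kneeToAnkle) != 1L || is.na(object@kneeToAnkle))
    msg <- c(msg, "'kneeToAnkle' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' MuscleMask: a binary muscle region aligned to a CTVolume
#'
#' @slot mask 3D logical array, same shape as the source volume.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot zRange Integer length-2, inclusive slice interval (knee to ankle)
#'   the mask is restricted to.
#'
#' @seealso [muscleMask()], [maskData()], [zRange()].
#' @export
setClass("MuscleMask",
  representation(mask = "array", spacing = "numeric", zRange = "integer")
)

setValidity("MuscleMask", function(object) {
  msg <- character()
  d <- dim(object@mask)
  if (length(d) != 3L) msg <- c(msg, "'mask' must be a 3D array")
  if (!is.logical(object@mask)) msg <- c(msg, "'mask' must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive values (mm)")
  if (length(object@zRange) != 2L)
    msg <- c(msg, "'zRange' must be two slice indices")
  else if (length(d) == 3L &&
           (object@zRange[1] < 1L || object@zRange[2] > d[3] ||
            object@zRange[1] > object@zRange[2]))
    msg <- c(msg, "'zRange' must be an ordered interval inside the volume")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic lower-leg phantom
#'
#' Describes the stylised two-bone lower-leg phantom: grid geometry and
#' per-tissue HU distributions, the intramuscular-fat fraction, the
#' severe-group distal HU offset, additive noise, between-subject
#' variability used at cohort level, and the master seed.
#'
#' @slot gridShape Integer length-3, voxels per axis (all >= 8).
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot tissueParams Named list; each element `c(mean =, sd =)` in HU for
#'   tissues `muscle_mild`, `muscle_severe`, `subcutaneous_fat`,
#'   `intramuscular_fat`, `cortical_bone`, `marrow`, `artery_contrast`,
#'   `vein`, `air`.
#' @slot imfFraction Fraction of muscle voxels replaced by intramuscular
#'   fat, in `[0, 1]`.
#' @slot distalGradient HU offset (usually negative) applied along the
#'   knee-to-ankle axis to severe subjects' muscle.
#' @slot distalProfile `"peaked"` (default; offset peaks at 70% of the
#'   leg and recedes toward the ankle) or `"linear"`.
#' @slot noiseSD Additive HU noise standard deviation applied to the
#'   whole grid before integer rounding.
#' @slot subjectMuSD Between-subject SD of the muscle mean HU, applied by
#'   [generateCohort()] only.
#' @slot subjectSigmaSD Between-subject SD of the muscle voxel SD,
#'   applied by [generateCohort()] only.
#' @slot seed Integer master seed.
#'
#' @seealso [phantomSpec()] for the constructor with the calibrated
#'   defaults.
#' @export
setClass("PhantomSpec",
  representation(
    gridShape = "integer", spacing = "numeric", tissueParams = "list",
    imfFraction = "numeric", distalGradient = "numeric",
    distalProfile = "character", noiseSD = "numeric",
    subjectMuSD = "numeric", subjectSigmaSD = "numeric", seed = "integer"
  )
)

.requiredTissues <- c(
  "muscle_mild", "muscle_severe", "subcutaneous_fat", "intramuscular_fat",
  "cortical_bone", "marrow", "artery_contrast", "vein", "air"
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "'gridShape' must be 3 integers, all >= 8")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive values (mm)")
  missing <- setdiff(.requiredTissues, names(object@tissueParams))
  if (length(missing))
    msg <- c(msg, paste0("tissueParams missing: ",
                         paste(missing, collapse = ", ")))
  for (nm in names(object@tissueParams)) {
    p <- object@tissueParams[[nm]]
    if (!all(c("mean", "sd") %in% names(p)) || p[["sd"]] < 0)
      msg <- c(msg, paste0("tissue '", nm,
                           "' needs a mean and a non-negative sd"))
  }
  if (object@imfFraction < 0 || object@imfFraction > 1)
    msg <- c(msg, "'imfFraction' must lie in [0, 1]")
  if (!object@distalProfile %in% c("peaked", "linear"))
    msg <- c(msg, "'distalProfile' must be \"peaked\" or \"linear\"")
  if (object@noiseSD < 0) msg <- c(msg, "'noiseSD' must be >= 0")
  if (object@subjectMuSD < 0 || object@subjectSigmaSD < 0)
    msg <- c(msg, "between-subject SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SegmentationParams: threshold window and cleanup settings
#'
#' @slot huLow,huHigh Inclusive HU window for muscle (defaults -10, 100).
#' @slot minComponentVoxels Minimum 3D connected-component size kept
#'   after thresholding.
#' @slot boneHuMin HU at or above which a voxel counts as cortical bone
#'   for the per-slice marrow enclosure rule (default 300).
#'
#' @seealso [segmentationParams()].
#' @export
setClass("SegmentationParams",
  representation(huLow = "numeric", huHigh = "numeric",
                 minComponentVoxels = "integer", boneHuMin = "numeric")
)

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@huLow >= object@huHigh)
    msg <- c(msg, "'huLow' must be below 'huHigh'")
  if (object@minComponentVoxels < 1L)
    msg <- c(msg, "'minComponentVoxels' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' DiscretizationParams: gray-level binning and neighbourhood settings
#'
#' @slot binWidth Fixed HU bin width (default 5), anchored at the ROI
#'   minimum.
#' @slot distance Neighbour distance in voxels (default 1).
#' @slot mode `"3d"` (13 unique directions over the whole ROI, default)
#'   or `"2d"` (in-plane neighbourhoods, matrices pooled over slices).
#'
#' @seealso [discretizationParams()].
#' @export
setClass("DiscretizationParams",
  representation(binWidth = "numeric", distance = "integer",
                 mode = "character")
)

setValidity("DiscretizationParams", function(object) {
  msg <- character()
  if (object@binWidth <= 0) msg <- c(msg, "'binWidth' must be positive")
  if (object@distance < 1L) msg <- c(msg, "'distance' must be >= 1")
  if (!object@mode %in% c("3d", "2d"))
    msg <- c(msg, "'mode' must be \"3d\" or \"2d\"")
  if (length(msg)) msg else TRUE
})
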