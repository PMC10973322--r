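## Shape features of a binary muscle mask.

.shapeNames <- paste0("shape_", c(
  "VolumeCm3", "MeanSliceAreaCm2", "MeshVolume", "VoxelVolume",
  "SurfaceArea", "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter",
  "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
  "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
  "LeastAxisLength", "Elongation", "Flatness"
))

# exposed voxel faces per axis direction; returns total area (mm^2) and a
# logical array marking boundary voxels
.surface <- function(m, sp) {
  d <- dim(m)
  shift <- function(ax, by) {
    out <- array(FALSE, d)
    if (ax == 1) {
      if (by > 0) out[-1, , ] <- m[-d[1], , ] else out[-d[1], , ] <- m[-1, , ]
    } else if (ax == 2) {
      if (by > 0) out[, -1, ] <- m[, -d[2], ] else out[, -d[2], ] <- m[, -1, ]
    } else {
      if (by > 0) out[, , -1] <- m[, , -d[3]] else out[, , -d[3]] <- m[, , -1]
    }
    out
  }
  faceArea <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- 0
  boundary <- array(FALSE, d)
  for (ax in 1:3) for (by in c(-1, 1)) {
    exposed <- m & !shift(ax, by)
    area <- area + sum(exposed) * faceArea[ax]
    boundary <- boundary | exposed
  }
  list(area = area, boundary = boundary)
}

# maximum pairwise distance between voxel centres.  The farthest pair
# lies on the convex hull, and every hull vertex is an axis extreme
# among the voxels sharing its other grid coordinates, so restricting to
# per-line min/max along each axis is exact and shrinks the quadratic
# scan considerably.  'idx' are the integer grid indices of the rows.
.maxPairDist <- function(coords, idx = NULL) {
  k <- nrow(coords)
  if (k < 2) return(0)
  p <- ncol(coords)
  if (!is.null(idx) && k > 256) {
    keep <- logical(k)
    K <- max(idx) + 1
    for (ax in seq_len(p)) {
      others <- setdiff(seq_len(p), ax)
      key <- idx[, others[1]]
      for (c in others[-1]) key <- key * K + idx[, c]
      o <- order(key, idx[, ax])
      firsts <- !duplicated(key[o])
      keep[o[firsts]] <- TRUE                      # per-line minima
      keep[o[c(firsts[-1], TRUE)]] <- TRUE         # per-line maxima
    }
    coords <- coords[keep, , drop = FALSE]
  }
  .cpp_max_pair_dist(coords)
}

#' Shape features of a muscle mask
#'
#' Two conventional features -- total muscle volume in cm^3 and the mean
#' per-slice cross-sectional area in cm^2 over non-empty slices -- plus
#' 14 radiomic shape features.  The surface is the set of exposed voxel
#' faces; mesh volume is obtained from that axis-aligned boundary surface
#' by the divergence theorem and therefore equals voxel count times voxel
#' volume.  Maximum diameters are pairwise distances between boundary
#' voxel centres (in-plane for the 2D variants); axis lengths are
#' `4 * sqrt(eigenvalue)` of the covariance of the physical voxel
#' coordinates.  For a single-voxel mask the axis lengths and diameters
#' are 0 and elongation/flatness are defined as 1.
#'
#' @param mask A [MuscleMask-class].
#' @param spacing Voxel spacing in mm (defaults to the mask's).
#' @return Named numeric vector of the 16 `shape_*` features.
#' @examples
#' m <- array(FALSE, c(12, 12, 12)); m[2:11, 2:11, 2:11] <- TRUE
#' shapeFeatures(muscleMask(m, spacing = c(1, 1, 1)))
#' @export
shapeFeatures <- function(mask, spacing = NULL) {
  stopifnot(is(mask, "MuscleMask"))
  m <- maskData(mask)
  if (!any(m)) stop("empty mask")
  bb <- .maskBBox(m)  # exact: every feature is translation-invariant
  m <- m[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
         bb[[3]][1]:bb[[3]][2], drop = FALSE]
  sp <- if (is.null(spacing)) voxelSpacing(mask) else as.numeric(spacing)
  n <- sum(m)
  voxelVol <- n * prod(sp)

  sliceCounts <- apply(m, 3, sum)
  meanArea <- mean(sliceCounts[sliceCounts > 0]) * sp[1] * sp[2] / 100

  surf <- .surface(m, sp)
  sphericity <- (pi^(1 / 3) * (6 * voxelVol)^(2 / 3)) / surf$area

  idx <- which(m, arr.ind = TRUE)
  coords <- sweep(idx, 2, sp, "*")

  bidx <- which(surf$boundary, arr.ind = TRUE)
  bco <- sweep(bidx, 2, sp, "*")
  max3d <- .maxPairDist(bco, bidx)
  maxPlane <- function(groupCol, keepCols) {
    if (nrow(bco) < 2) return(0)
    grp <- split(seq_len(nrow(bco)), bidx[, groupCol])
    max(vapply(grp, function(rows)
      .maxPairDist(bco[rows, keepCols, drop = FALSE]), 0))
  }
  max2dSlice <- maxPlane(3, 1:2)
  max2dColumn <- maxPlane(2, c(1, 3))
  max2dRow <- maxPlane(1, 2:3)

  if (n > 1) {
    ev <- sort(eigen(stats::cov(coords), only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    axes <- 4 * sqrt(ev)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  } else {
    axes <- c(0, 0, 0); elong <- 1; flat <- 1
  }

  out <- c(voxelVol / 1000, meanArea, voxelVol, voxelVol, surf$area,
           surf$area / voxelVol, sphericity, max3d, max2dSlice,
           max2dColumn, max2dRow, axes[1], axes[2], axes[3], elong, flat)
  names(out) <- .shapeNames
  out
}
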