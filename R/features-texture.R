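## Gray-level texture features (GLCM, GLDM, GLRLM, GLSZM, NGTDM).
##
## All families operate on the same discretisation: fixed-width HU bins
## anchored at the ROI minimum, levels 1..ng.  In "3d" mode matrices are
## accumulated over the whole ROI with 13 unique directions (26
## neighbours for the dependence/gray-tone families); in "2d" mode the
## in-plane equivalents are used and matrices pool over slices.
## Direction-wise matrices (GLCM, GLRLM) yield one feature value per
## direction, averaged afterwards.

.glcmNames <- paste0("glcm_", c(
  "Autocorrelation", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
  "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
  "JointEntropy", "MCC", "MaximumProbability", "SumAverage", "SumEntropy",
  "SumSquares"
))

.gldmNames <- paste0("gldm_", c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis"
))

.glrlmNames <- paste0("glrlm_", c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage",
  "GrayLevelVariance", "RunVariance", "RunEntropy",
  "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
  "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
  "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"
))

.glszmNames <- paste0("glszm_", c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage",
  "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
  "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
  "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
  "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"
))

.ngtdmNames <- paste0("ngtdm_", c(
  "Coarseness", "Contrast", "Busyness", "Complexity", "Strength"
))

# bounding-box ranges of a mask (all texture families only look at
# in-ROI voxels, so cropping to the box is exact)
.maskBBox <- function(m) {
  lapply(1:3, function(ax) {
    any <- apply(m, ax, any)
    range(which(any))
  })
}

# discretised level array: 0 outside the ROI, 1..ng inside; cropped to
# the mask bounding box
.levelArray <- function(volume, mask, disc) {
  hu <- huData(volume)
  m <- maskData(mask)
  stopifnot(identical(dim(hu), dim(m)))
  if (!any(m)) stop("empty mask")
  bb <- .maskBBox(m)
  xr <- bb[[1]][1]:bb[[1]][2]
  yr <- bb[[2]][1]:bb[[2]][2]
  zr <- bb[[3]][1]:bb[[3]][2]
  hu <- hu[xr, yr, zr, drop = FALSE]
  m <- m[xr, yr, zr, drop = FALSE]
  lev <- .binLevels(hu[m], disc@binWidth)
  arr <- array(0L, dim(hu))
  arr[m] <- lev
  list(arr = arr, ng = max(lev), dims = .storageDim(arr), n = sum(m))
}

.pairDirs <- function(disc) {
  d <- if (disc@mode == "2d") .dirs2d4() else .offsets13()
  d * as.integer(disc@distance)
}

.neighOffsets <- function(disc) {
  d <- if (disc@mode == "2d") .offsets2d8() else .offsets26()
  d * as.integer(disc@distance)
}

# --- GLCM -------------------------------------------------------------------

# features of one normalised symmetric co-occurrence matrix
.glcmFromP <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)            # == colSums for a symmetric matrix
  mux <- sum(i * P)
  sigx <- sqrt(sum((i - mux)^2 * P))

  # diagonal-band marginals
  kd <- 0:(ng - 1)
  pxmy <- vapply(kd, function(k) sum(P[abs(i - j) == k]), 0)
  ks <- 2:(2 * ng)
  pxpy <- vapply(ks, function(k) sum(P[(i + j) == k]), 0)

  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent(P)
  hx <- ent(px)
  pxpyOuter <- px %o% px
  sel <- P > 0
  hxy1 <- -sum(P[sel] * log2(pxpyOuter[sel]))
  sel2 <- pxpyOuter > 0
  hxy2 <- -sum(pxpyOuter[sel2] * log2(pxpyOuter[sel2]))

  da <- sum(kd * pxmy)
  corr <- if (sigx > 0) (sum(i * j * P) - mux^2) / sigx^2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0

  present <- which(px > 0)
  mcc <- if (length(present) > 1) {
    Psub <- P[present, present, drop = FALSE]
    pxs <- px[present]
    # Q(a, b) = sum_k P(a,k) P(b,k) / (px(a) py(k))
    Q <- sweep(Psub, 1, pxs, "/") %*% t(sweep(Psub, 2, pxs, "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(min(ev[2], 1), 0))
  } else 1

  c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - 2 * mux)^4 * P),
    ClusterShade = sum((i + j - 2 * mux)^3 * P),
    ClusterTendency = sum((i + j - 2 * mux)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pxmy),
    DifferenceVariance = sum((kd - da)^2 * pxmy),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * pxpy),
    SumEntropy = ent(pxpy),
    SumSquares = sum((i - mux)^2 * P)
  )
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric, normalised co-occurrence matrices are accumulated per
#' direction over in-ROI neighbour pairs only, the 24 standard features
#' are computed per direction and then averaged over directions.
#' Directions without any voxel pair are dropped from the average.  With
#' a single gray level, Correlation and MCC are defined as 1 and
#' Imc1/Imc2 as 0.
#'
#' @param volume A [CTVolume-class].
#' @param mask A [MuscleMask-class] with at least 2 in-ROI voxels.
#' @param disc A [DiscretizationParams-class].
#' @return Named numeric vector of the 24 `glcm_*` features.
#' @export
glcmFeatures <- function(volume, mask, disc = discretizationParams()) {
  .glcmFromLA(.levelArray(volume, mask, disc), disc)
}

.glcmFromLA <- function(la, disc) {
  if (la$n < 2) stop("GLCM needs at least 2 in-mask voxels")
  dirs <- .pairDirs(disc)
  counts <- .cpp_glcm_counts(la$arr, la$dims, dirs, la$ng)
  acc <- NULL
  used <- 0L
  for (d in seq_len(nrow(dirs))) {
    Cd <- counts[, , d, drop = TRUE]
    Cd <- matrix(Cd, la$ng, la$ng)
    tot <- sum(Cd)
    if (tot == 0) next
    f <- .glcmFromP(Cd / tot)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1L
  }
  if (used == 0L) stop("no in-mask voxel pairs in any direction")
  out <- acc / used
  names(out) <- .glcmNames
  out
}

# --- GLDM -------------------------------------------------------------------

.gldmFromCounts <- function(counts) {
  Nz <- sum(counts)
  p <- counts / Nz
  ng <- nrow(p)
  nd <- ncol(p)
  i <- matrix(seq_len(ng), ng, nd)
  j <- matrix(seq_len(nd), ng, nd, byrow = TRUE)  # dependence + 1
  pg <- rowSums(counts)
  pd <- colSums(counts)
  mui <- sum(i * p)
  muj <- sum(j * p)
  pp <- p[p > 0]
  c(
    SmallDependenceEmphasis = sum(p / j^2),
    LargeDependenceEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(pg^2) / Nz,
    DependenceNonUniformity = sum(pd^2) / Nz,
    DependenceNonUniformityNormalized = sum(pd^2) / Nz^2,
    GrayLevelVariance = sum(p * (i - mui)^2),
    DependenceVariance = sum(p * (j - muj)^2),
    DependenceEntropy = -sum(pp * log2(pp)),
    LowGrayLevelEmphasis = sum(p / i^2),
    HighGrayLevelEmphasis = sum(p * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
}

#' Gray-level dependence matrix features
#'
#' A neighbour is dependent on the centre voxel iff the absolute level
#' difference is at most `alpha` (default 0).  The recorded dependence of
#' a voxel is its dependent-neighbour count; feature weights use
#' `k = count + 1` (a voxel depends on itself), which keeps all 14
#' features finite -- an isolated voxel falls in the dependence-0 bin.
#'
#' @inheritParams glcmFeatures
#' @param alpha Level-difference tolerance (default 0).
#' @return Named numeric vector of the 14 `gldm_*` features.
#' @export
gldmFeatures <- function(volume, mask, disc = discretizationParams(),
                         alpha = 0L) {
  .gldmFromLA(.levelArray(volume, mask, disc), disc, alpha)
}

.gldmFromLA <- function(la, disc, alpha = 0L) {
  off <- .neighOffsets(disc)
  counts <- .cpp_gldm_counts(la$arr, la$dims, off, la$ng,
                             as.integer(alpha))
  counts <- counts[, seq_len(max(which(colSums(counts) > 0))), drop = FALSE]
  out <- .gldmFromCounts(counts)
  names(out) <- .gldmNames
  out
}

# --- GLRLM ------------------------------------------------------------------

.glrlmFromCounts <- function(counts, np) {
  Nr <- sum(counts)
  p <- counts / Nr
  ng <- nrow(p)
  nl <- ncol(p)
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  pg <- rowSums(counts)
  pr <- colSums(counts)
  mui <- sum(i * p)
  muj <- sum(j * p)
  pp <- p[p > 0]
  c(
    ShortRunEmphasis = sum(p / j^2),
    LongRunEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(pg^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / Nr^2,
    RunLengthNonUniformity = sum(pr^2) / Nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / Nr^2,
    RunPercentage = Nr / np,
    GrayLevelVariance = sum(p * (i - mui)^2),
    RunVariance = sum(p * (j - muj)^2),
    RunEntropy = -sum(pp * log2(pp)),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    HighGrayLevelRunEmphasis = sum(p * i^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    ShortRunHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LongRunLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LongRunHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
}

#' Gray-level run-length matrix features
#'
#' Maximal equal-level runs are counted along each direction (volume
#' borders and out-of-ROI voxels break runs); the 16 standard features
#' are computed per direction and averaged.
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of the 16 `glrlm_*` features.
#' @export
glrlmFeatures <- function(volume, mask, disc = discretizationParams()) {
  .glrlmFromLA(.levelArray(volume, mask, disc), disc)
}

.glrlmFromLA <- function(la, disc) {
  dirs <- if (disc@mode == "2d") .dirs2d4() else .offsets13()
  counts <- .cpp_glrlm_counts(la$arr, la$dims, dirs, la$ng)
  acc <- NULL
  for (d in seq_len(nrow(dirs))) {
    Cd <- matrix(counts[, , d, drop = TRUE], la$ng, dim(counts)[2])
    keep <- max(which(colSums(Cd) > 0))
    f <- .glrlmFromCounts(Cd[, seq_len(keep), drop = FALSE], la$n)
    acc <- if (is.null(acc)) f else acc + f
  }
  out <- acc / nrow(dirs)
  names(out) <- .glrlmNames
  out
}

# --- GLSZM ------------------------------------------------------------------

.glszmFromZones <- function(zones, ng, np) {
  counts <- matrix(0, ng, max(zones[, 2]))
  for (r in seq_len(nrow(zones)))
    counts[zones[r, 1], zones[r, 2]] <- counts[zones[r, 1], zones[r, 2]] + 1
  Nz <- sum(counts)
  p <- counts / Nz
  nl <- ncol(p)
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  pg <- rowSums(counts)
  ps <- colSums(counts)
  mui <- sum(i * p)
  muj <- sum(j * p)
  pp <- p[p > 0]
  c(
    SmallAreaEmphasis = sum(p / j^2),
    LargeAreaEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(pg^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(pg^2) / Nz^2,
    SizeZoneNonUniformity = sum(ps^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(ps^2) / Nz^2,
    ZonePercentage = Nz / np,
    GrayLevelVariance = sum(p * (i - mui)^2),
    ZoneVariance = sum(p * (j - muj)^2),
    ZoneEntropy = -sum(pp * log2(pp)),
    LowGrayLevelZoneEmphasis = sum(p / i^2),
    HighGrayLevelZoneEmphasis = sum(p * i^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallAreaHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeAreaLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
}

#' Gray-level size-zone matrix features
#'
#' Zones are connected sets of equal-level voxels (26-connected in 3D
#' mode, 8-connected in-plane in 2D mode).
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of the 16 `glszm_*` features.
#' @export
glszmFeatures <- function(volume, mask, disc = discretizationParams()) {
  .glszmFromLA(.levelArray(volume, mask, disc), disc)
}

.glszmFromLA <- function(la, disc) {
  conn <- if (disc@mode == "2d") .offsets2d8() else .offsets26()
  zones <- .cpp_glszm_zones(la$arr, la$dims, conn)
  out <- .glszmFromZones(zones, la$ng, la$n)
  names(out) <- .glszmNames
  out
}

# --- NGTDM ------------------------------------------------------------------

.ngtdmFromCounts <- function(nsi, ng) {
  ni <- nsi[, 1]
  si <- nsi[, 2]
  N <- sum(ni)
  p <- ni / N
  present <- which(p > 0)
  ngp <- length(present)
  iv <- seq_len(ng)

  coarseness <- if (sum(p * si) > 0) 1 / sum(p * si) else 1e6

  contrast <- if (ngp > 1) {
    s1 <- 0
    for (a in present) for (b in present)
      s1 <- s1 + p[a] * p[b] * (a - b)^2
    (s1 / (ngp * (ngp - 1))) * (sum(si) / N)
  } else 0

  denB <- 0
  for (a in present) for (b in present)
    denB <- denB + abs(iv[a] * p[a] - iv[b] * p[b])
  busyness <- if (denB > 0) sum(p * si) / denB else 0

  complexity <- 0
  for (a in present) for (b in present)
    complexity <- complexity +
      abs(a - b) * (p[a] * si[a] + p[b] * si[b]) / (p[a] + p[b])
  complexity <- complexity / N

  strength <- if (sum(si) > 0) {
    s2 <- 0
    for (a in present) for (b in present)
      s2 <- s2 + (p[a] + p[b]) * (a - b)^2
    s2 / sum(si)
  } else 0

  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' Neighbouring gray-tone difference matrix features
#'
#' For every in-ROI voxel with at least one in-ROI neighbour, the
#' absolute difference between its level and the mean level of its
#' in-ROI neighbours is accumulated per level.
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of the 5 `ngtdm_*` features.
#' @export
ngtdmFeatures <- function(volume, mask, disc = discretizationParams()) {
  .ngtdmFromLA(.levelArray(volume, mask, disc), disc)
}

.ngtdmFromLA <- function(la, disc) {
  off <- .neighOffsets(disc)
  nsi <- .cpp_ngtdm_counts(la$arr, la$dims, off, la$ng)
  out <- .ngtdmFromCounts(nsi, la$ng)
  names(out) <- .ngtdmNames
  out
}
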