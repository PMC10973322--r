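## Synthetic lower-leg CTA phantom.
##
## The phantom is a stylised two-bone leg: an elliptical skin/fat ring, a
## muscle compartment filling the interior, tibia and fibula analogues
## (cortical shell around a marrow core), three contrast-filled arteries
## inside the muscle, and two subcutaneous veins in the fat ring.  Only
## HU composition and structural adjacency matter: marrow lies inside the
## muscle HU window but is enclosed by cortical bone, and veins lie
## inside the window but form small isolated per-slice components, so
## both must be removed structurally by the segmentation stage.

# tissue codes in the truth grid
.TISSUE <- c(air = 0L, subcutaneous_fat = 1L, muscle = 2L,
             cortical_bone = 3L, marrow = 4L, artery_contrast = 5L,
             vein = 6L, intramuscular_fat = 7L)

# geometry in fractions of a 64-voxel reference grid
.GEOM <- list(
  skin     = c(a = 19.5, b = 17.5),
  muscle   = c(a = 15.5, b = 13.5),
  tibia    = c(cx = -5.5, cy = -5.5, r = 4.5, marrow = 2.5),
  fibula   = c(cx = 7.5,  cy = 6.5,  r = 2.8, marrow = 1.4),
  arteries = list(c(cx = 1.5, cy = -4.5, r = 1.2),
                  c(cx = -4.5, cy = 5.5, r = 1.2),
                  c(cx = 2.5, cy = 9.5, r = 1.2)),
  veins    = list(c(cx = 0, cy = -16.5, r = 1.0),
                  c(cx = -17.5, cy = 0, r = 1.0))
)

# deterministic 32-bit hash of a subject id
.idHash <- function(id) {
  h <- 0
  for (b in utf8ToInt(as.character(id))) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Create a subject record
#'
#' @param subject_id Character id.
#' @param group `"mild"` (DSA runoff score <= 7) or `"severe"` (> 7).
#' @param dsa_score,cta_score Runoff scores in `[0, 19]` (may be `NA`
#'   before scoring).
#' @param covariates Optional named list (age, sex, ...).
#' @return A list of class `SubjectRecord`.
#' @export
subjectRecord <- function(subject_id, group, dsa_score = NA_real_,
                          cta_score = NA_real_, covariates = list()) {
  group <- match.arg(group, c("mild", "severe"))
  if (!is.na(dsa_score)) {
    if (dsa_score < 0 || dsa_score > 19)
      stop("dsa_score must lie in [0, 19]")
    if ((group == "mild") != (dsa_score <= 7))
      stop("group label inconsistent with DSA score dichotomisation at 7")
  }
  if (!is.na(cta_score) && (cta_score < 0 || cta_score > 19))
    stop("cta_score must lie in [0, 19]")
  structure(list(subject_id = as.character(subject_id), group = group,
                 dsa_score = dsa_score, cta_score = cta_score,
                 covariates = covariates),
            class = "SubjectRecord")
}

# per-slice tissue label grid; errors if a structure has no voxels
.sliceLabels <- function(nx, ny) {
  s <- min(nx, ny) / 64
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  x <- matrix(seq_len(nx), nx, ny) - cx
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE) - cy
  lab <- matrix(.TISSUE[["air"]], nx, ny)

  inEllipse <- function(a, b) (x / (a * s))^2 + (y / (b * s))^2 <= 1
  inDisk <- function(p) (x - p[["cx"]] * s)^2 + (y - p[["cy"]] * s)^2 <=
    (p[["r"]] * s)^2

  paint <- function(lab, sel, code, what) {
    if (!any(sel))
      stop("phantom structure '", what, "' has no voxels at this grid size")
    lab[sel] <- code
    lab
  }

  lab <- paint(lab, inEllipse(.GEOM$skin[["a"]], .GEOM$skin[["b"]]),
               .TISSUE[["subcutaneous_fat"]], "subcutaneous_fat")
  lab <- paint(lab, inEllipse(.GEOM$muscle[["a"]], .GEOM$muscle[["b"]]),
               .TISSUE[["muscle"]], "muscle")
  for (bone in c("tibia", "fibula")) {
    p <- .GEOM[[bone]]
    lab <- paint(lab, inDisk(p), .TISSUE[["cortical_bone"]],
                 paste0(bone, "_cortex"))
    lab <- paint(lab, inDisk(c(cx = p[["cx"]], cy = p[["cy"]],
                               r = p[["marrow"]])),
                 .TISSUE[["marrow"]], paste0(bone, "_marrow"))
  }
  for (i in seq_along(.GEOM$arteries))
    lab <- paint(lab, inDisk(.GEOM$arteries[[i]]), .TISSUE[["artery_contrast"]],
                 paste0("artery_", i))
  for (i in seq_along(.GEOM$veins))
    lab <- paint(lab, inDisk(.GEOM$veins[[i]]), .TISSUE[["vein"]],
                 paste0("vein_", i))
  lab
}

# distal HU offset weight along the knee->ankle axis, in [0, 1]
.distalWeight <- function(nz, profile) {
  t <- if (nz > 1) (seq_len(nz) - 1) / (nz - 1) else 0
  switch(profile,
    linear = t,
    peaked = ifelse(t <= 0.7, (t / 0.7)^2, 1 - 0.7 * (t - 0.7) / 0.3)
  )
}

#' Generate a synthetic lower-leg CTA volume
#'
#' Draws every tissue's voxels from its configured HU distribution; the
#' muscle compartment uses the subject's group parameters
#' (`muscle_mild` / `muscle_severe`).  A fraction `imfFraction` of muscle
#' voxels is replaced by intramuscular-fat speckle, severe subjects
#' receive the distal HU offset, optional grid-wide noise is added, and
#' HU are rounded to integers and clamped to `[-1024, 3071]`.
#' Deterministic given `(spec seed, subject_id)`.
#'
#' @param spec A [PhantomSpec-class].
#' @param subject A [subjectRecord()] (group and id are used).
#' @param withTruth If `TRUE`, also return the tissue truth grid.
#' @return A [CTVolume-class], or (with `withTruth`) a list with elements
#'   `volume`, `truth` (integer tissue codes) and `muscle` (logical
#'   ground-truth muscle grid, intramuscular fat excluded).
#' @examples
#' spec <- phantomSpec(gridShape = c(32, 32, 8), seed = 7L)
#' vol <- generatePhantom(spec, subjectRecord("S1", "mild"))
#' @export
generatePhantom <- function(spec, subject, withTruth = FALSE) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  nx <- spec@gridShape[1]; ny <- spec@gridShape[2]; nz <- spec@gridShape[3]
  set.seed(as.integer((as.numeric(spec@seed) +
                         .idHash(subject$subject_id)) %% 2147483647))

  lab <- array(rep(.sliceLabels(nx, ny), nz), c(nx, ny, nz))

  # intramuscular-fat speckles
  if (spec@imfFraction > 0) {
    mus <- which(lab == .TISSUE[["muscle"]])
    nImf <- round(spec@imfFraction * length(mus))
    if (nImf > 0)
      lab[sample(mus, nImf)] <- .TISSUE[["intramuscular_fat"]]
  }

  muscleTissue <- if (subject$group == "mild") "muscle_mild" else
    "muscle_severe"
  hu <- array(0, c(nx, ny, nz))
  codeToTissue <- c("air", "subcutaneous_fat", muscleTissue,
                    "cortical_bone", "marrow", "artery_contrast", "vein",
                    "intramuscular_fat")
  for (code in 0:7) {
    idx <- which(lab == code)
    if (!length(idx)) next
    p <- spec@tissueParams[[codeToTissue[code + 1]]]
    hu[idx] <- if (p[["sd"]] > 0)
      rnorm(length(idx), p[["mean"]], p[["sd"]]) else p[["mean"]]
  }

  if (subject$group == "severe" && spec@distalGradient != 0) {
    w <- .distalWeight(nz, spec@distalProfile) * spec@distalGradient
    offset <- array(rep(w, each = nx * ny), c(nx, ny, nz))
    sel <- lab == .TISSUE[["muscle"]]
    hu[sel] <- hu[sel] + offset[sel]
  }

  if (spec@noiseSD > 0)
    hu <- hu + rnorm(length(hu), 0, spec@noiseSD)

  hu <- array(pmin(pmax(round(hu), -1024), 3071), c(nx, ny, nz))
  vol <- ctVolume(hu, spacing = spec@spacing, kneeToAnkle = TRUE)
  if (!withTruth) return(vol)
  list(volume = vol, truth = lab, muscle = lab == .TISSUE[["muscle"]])
}

# group-conditional runoff score parameters (DSA / CTA group summaries)
.runoffParams <- list(
  mild   = c(dsaMean = 3.3,  dsaSD = 2.6, ctaMean = 6.1,  ctaSD = 4.0),
  severe = c(dsaMean = 12.3, dsaSD = 3.0, ctaMean = 11.8, ctaSD = 5.1)
)

#' Sample correlated DSA and CTA runoff scores for one subject
#'
#' DSA scores are drawn from the group-conditional normal (mild 3.3 +/-
#' 2.6, severe 12.3 +/- 3.0), clipped to `[0, 19]` and rejected-resampled
#' until consistent with the group's side of the dichotomisation boundary
#' (mild <= 7, severe > 7).  The CTA score is generated conditionally on
#' the DSA score with correlation `rho` and the group CTA summaries (mild
#' 6.1 +/- 4.0, severe 11.8 +/- 5.1), clipped to `[0, 19]`.
#'
#' @param group `"mild"` or `"severe"`.
#' @param seed Optional integer seed.
#' @param rho Latent DSA-CTA correlation (default 0.8).
#' @param dsaSD,ctaSD Optional overrides of the group SDs (set to 0 for a
#'   deterministic draw at the group mean).
#' @return Named numeric `c(dsa_score =, cta_score =)`.
#' @examples
#' sampleRunoffScores("mild", seed = 1L)
#' @export
sampleRunoffScores <- function(group, seed = NULL, rho = 0.8,
                               dsaSD = NULL, ctaSD = NULL) {
  group <- match.arg(group, c("mild", "severe"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- .runoffParams[[group]]
  if (is.null(dsaSD)) dsaSD <- p[["dsaSD"]]
  if (is.null(ctaSD)) ctaSD <- p[["ctaSD"]]
  ok <- if (group == "mild") function(s) s <= 7 else function(s) s > 7
  dsa <- NA_real_
  for (i in seq_len(1000L)) {
    cand <- min(max(rnorm(1, p[["dsaMean"]], dsaSD), 0), 19)
    if (ok(cand)) { dsa <- cand; break }
  }
  if (is.na(dsa)) stop("runoff score rejection sampling did not converge")
  ctaMu <- p[["ctaMean"]] +
    (if (dsaSD > 0) rho * (ctaSD / dsaSD) * (dsa - p[["dsaMean"]]) else 0)
  cta <- ctaMu + (if (ctaSD > 0) rnorm(1, 0, ctaSD * sqrt(1 - rho^2)) else 0)
  c(dsa_score = dsa, cta_score = min(max(cta, 0), 19))
}

#' Generate a synthetic cohort
#'
#' Produces `nMild + nSevere` subjects with correlated DSA/CTA runoff
#' scores and one phantom volume each.  Between-subject variability is
#' applied here: each subject's muscle mean HU is jittered by
#' `N(0, subjectMuSD)` and the muscle voxel SD by `N(0, subjectSigmaSD)`
#' around the group parameters.  Per-subject seeds are derived
#' reproducibly from the master seed, so the whole cohort is a pure
#' function of `(nMild, nSevere, spec, seed)`.
#'
#' @param nMild,nSevere Group sizes (defaults 36 and 20, the study's).
#' @param spec A [PhantomSpec-class].
#' @param seed Master seed (defaults to the spec seed).
#' @param outDir If non-`NULL`, volumes are written as NIfTI files and a
#'   `subjects.csv` (`subject_id,group,dsa_score,cta_score`) into this
#'   directory, and `volumes` holds file paths instead of objects.
#' @param withTruth Keep ground-truth muscle grids (in-memory mode only).
#' @return List with `subjects` (data.frame) and `volumes` (list of
#'   [CTVolume-class] or file paths); with `withTruth`, also `muscle`
#'   truth grids.
#' @export
generateCohort <- function(nMild = 36L, nSevere = 20L, spec = phantomSpec(),
                           seed = NULL, outDir = NULL, withTruth = FALSE) {
  stopifnot(nMild >= 1L, nSevere >= 1L)
  validObject(spec)
  if (is.null(seed)) seed <- spec@seed
  n <- nMild + nSevere
  set.seed(as.integer(seed))
  subjectSeeds <- sample.int(2147483646L, n)
  muJitter <- rnorm(n, 0, spec@subjectMuSD)
  sdJitter <- rnorm(n, 0, spec@subjectSigmaSD)

  ids <- sprintf("S%03d", seq_len(n))
  groups <- c(rep("mild", nMild), rep("severe", nSevere))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  }

  volumes <- vector("list", n)
  muscles <- if (withTruth) vector("list", n) else NULL
  scores <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    scores[i, ] <- sampleRunoffScores(groups[i], seed = subjectSeeds[i])
    sspec <- spec
    sspec@seed <- subjectSeeds[i]
    tiss <- if (groups[i] == "mild") "muscle_mild" else "muscle_severe"
    sspec@tissueParams[[tiss]][["mean"]] <-
      sspec@tissueParams[[tiss]][["mean"]] + muJitter[i]
    sspec@tissueParams[[tiss]][["sd"]] <-
      max(0.1, sspec@tissueParams[[tiss]][["sd"]] + sdJitter[i])
    rec <- subjectRecord(ids[i], groups[i], scores[i, 1], scores[i, 2])
    gen <- generatePhantom(sspec, rec, withTruth = withTruth)
    if (withTruth) {
      muscles[[i]] <- gen$muscle
      gen <- gen$volume
    }
    if (!is.null(outDir)) {
      path <- file.path(outDir, paste0(ids[i], ".nii.gz"))
      writeVolume(gen, path)
      volumes[[i]] <- path
    } else {
      volumes[[i]] <- gen
    }
  }

  subjects <- data.frame(
    subject_id = ids, group = groups,
    dsa_score = scores[, 1], cta_score = scores[, 2],
    stringsAsFactors = FALSE
  )
  if (!is.null(outDir))
    write.csv(subjects, file.path(outDir, "subjects.csv"),
              row.names = FALSE)
  out <- list(subjects = subjects, volumes = volumes)
  if (withTruth) out$muscle <- muscles
  out
}
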