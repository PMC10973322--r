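
# 1 x n x 1 row volume with one in-plane direction only: use 2d mode with
# a mask confined to a single row so only the x direction has pairs
rowVolume <- function(values) {
  hu <- array(0, c(length(values), 1, 1))
  hu[, 1, 1] <- values
  ctVolume(hu)
}

test_that("GLCM on the worked 3-voxel row matches pair enumeration", {
  vol <- rowVolume(c(1, 1, 2))
  mask <- muscleMask(array(TRUE, dim(huData(vol))))
  disc <- discretizationParams(binWidth = 1)
  # pairs along x (both orders): (1,1) twice, (1,2) and (2,1) once each
  f <- glcmFeatures(vol, mask, disc)
  expect_equal(f[["glcm_MaximumProbability"]], 0.5)
  expect_equal(f[["glcm_JointEnergy"]], 0.375)
  expect_equal(f[["glcm_Contrast"]], 0.5)
})

test_that("GLCM on a constant volume is degenerate as documented", {
  vol <- ctVolume(array(7, c(4, 4, 4)))
  mask <- muscleMask(array(TRUE, c(4, 4, 4)))
  f <- glcmFeatures(vol, mask, discretizationParams(binWidth = 1))
  expect_equal(f[["glcm_Contrast"]], 0)
  expect_equal(f[["glcm_MaximumProbability"]], 1)
  expect_equal(f[["glcm_Correlation"]], 1)
  expect_equal(f[["glcm_Imc1"]], 0)
})

test_that("GLDM of a constant cube records plain neighbour counts", {
  vol <- ctVolume(array(5, c(3, 3, 3)))
  mask <- muscleMask(array(TRUE, c(3, 3, 3)))
  f <- gldmFeatures(vol, mask, discretizationParams(binWidth = 1))
  # brute-force dependence histogram: dependence = 26-neighbour count
  lev <- array(1L, c(3, 3, 3))
  expect_equal(f[["gldm_DependenceNonUniformity"]],
               oracleGldm(lev)[["gldm_DependenceNonUniformity"]])
  # centre voxel has all 26 neighbours dependent
  expect_equal(f[["gldm_LargeDependenceEmphasis"]],
               oracleGldm(lev)[["gldm_LargeDependenceEmphasis"]])
})

test_that("a single voxel lands in the dependence-0 bin with DNN = 1", {
  vol <- ctVolume(array(5, c(3, 3, 3)))
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  f <- gldmFeatures(vol, muscleMask(m), discretizationParams(binWidth = 1))
  expect_equal(f[["gldm_DependenceNonUniformityNormalized"]], 1)
  expect_equal(f[["gldm_SmallDependenceEmphasis"]], 1)  # k = count + 1
})

test_that("GLRLM on the worked 4-voxel row matches run enumeration", {
  vol <- rowVolume(c(1, 1, 1, 2))
  mask <- muscleMask(array(TRUE, dim(huData(vol))))
  f <- glrlmFeatures(vol, mask, discretizationParams(binWidth = 1,
                                                     mode = "2d"))
  # in-plane directions: x has runs {(1, len 3), (2, len 1)}; the other
  # three in-plane directions each see 4 unit runs
  expect_equal(f[["glrlm_ShortRunEmphasis"]],
               ((1 / 9 + 1) / 2 + 1 + 1 + 1) / 4)
})

test_that("constant image yields one zone and zero NGTDM contrast", {
  vol <- ctVolume(array(3, c(4, 4, 2)))
  mask <- muscleMask(array(TRUE, c(4, 4, 2)))
  disc <- discretizationParams(binWidth = 1)
  fz <- glszmFeatures(vol, mask, disc)
  expect_equal(fz[["glszm_ZonePercentage"]], 1 / 32)  # a single zone
  expect_equal(fz[["glszm_LargeAreaEmphasis"]], 32^2)
  fn <- ngtdmFeatures(vol, mask, disc)
  expect_equal(fn[["ngtdm_Contrast"]], 0)
  expect_equal(fn[["ngtdm_Busyness"]], 0)
})

test_that("all texture families match the brute-force oracle on random ROIs", {
  set.seed(101)
  disc <- discretizationParams(binWidth = 1)
  for (case in 1:10) {
    rv <- randomLevelVolume()
    got <- extractFeatures(rv$volume, rv$mask, disc,
                           families = c("glcm", "gldm", "glrlm",
                                        "glszm", "ngtdm"))
    want <- oracleTexture(rv$hu, rv$m, binWidth = 1)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
})

test_that("texture matrices are invariant to translating the ROI in the grid", {
  set.seed(5)
  core <- array(sample.int(4, 4^3, replace = TRUE), c(4, 4, 4))
  make <- function(ox, oy, oz) {
    hu <- array(0, c(12, 12, 12))
    m <- array(FALSE, c(12, 12, 12))
    hu[ox + 1:4, oy + 1:4, oz + 1:4] <- core
    m[ox + 1:4, oy + 1:4, oz + 1:4] <- TRUE
    extractFeatures(ctVolume(hu), muscleMask(m),
                    discretizationParams(binWidth = 1),
                    families = c("glcm", "gldm", "glrlm", "glszm",
                                 "ngtdm"))
  }
  expect_equal(make(0, 0, 0), make(5, 3, 6))
})

test_that("adding a constant HU leaves discretised texture features unchanged", {
  set.seed(6)
  hu <- array(sample(seq(0, 60, by = 5), 5^3, replace = TRUE), c(5, 5, 5))
  m <- muscleMask(array(TRUE, c(5, 5, 5)))
  disc <- discretizationParams(binWidth = 5)
  f1 <- extractFeatures(ctVolume(hu), m, disc,
                        families = c("glcm", "gldm", "ngtdm"))
  f2 <- extractFeatures(ctVolume(hu + 35), m, disc,
                        families = c("glcm", "gldm", "ngtdm"))
  expect_equal(f1, f2)
})

test_that("gray-level matrices are proper probability distributions", {
  set.seed(7)
  rv <- randomLevelVolume()
  la <- muscleCTA:::.levelArray(rv$volume, rv$mask,
                                discretizationParams(binWidth = 1))
  counts <- muscleCTA:::.cpp_glcm_counts(la$arr, la$dims,
                                         muscleCTA:::.offsets13(), la$ng)
  for (d in 1:13) {
    P <- matrix(counts[, , d], la$ng, la$ng)
    if (sum(P) == 0) next
    P <- P / sum(P)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))  # symmetric by construction
  }
})
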