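test_that("threshold window is inclusive on both bounds", {
  hu <- array(50, c(8, 8, 3))
  hu[1:4, 1, 1] <- c(-11, -10, 100, 101)
  vol <- ctVolume(hu)
  m <- maskData(thresholdSegment(vol))
  expect_identical(m[1:4, 1, 1], c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(m[, , 2:3]))  # constant-50 slices fully selected
})

test_that("threshold keeps marrow and veins but drops fat, bone and arteries", {
  g <- generatePhantom(smallSpec(seed = 21L), subjectRecord("S1", "mild"),
                       withTruth = TRUE)
  m <- maskData(thresholdSegment(g$volume))
  frac <- function(code) mean(m[g$truth == code])
  expect_gt(frac(4), 0.95)  # marrow (~30 HU) still inside the window
  expect_gt(frac(6), 0.80)  # vein (~90 HU) mostly inside
  expect_lt(frac(1), 0.01)  # subcutaneous fat excluded
  expect_lt(frac(3), 0.01)  # cortical bone excluded
  expect_lt(frac(5), 0.01)  # contrast artery excluded
})

test_that("cleanup removes bone-enclosed components via border flood fill", {
  # a synthetic slice: in-window disk fully enclosed by a cortical ring
  hu <- array(-500, c(21, 21, 3))
  for (x in 1:21) for (y in 1:21) {
    r <- sqrt((x - 11)^2 + (y - 11)^2)
    if (r <= 3) hu[x, y, ] <- 30          # marrow analog
    else if (r <= 6) hu[x, y, ] <- 800    # cortical ring
    else if (r <= 9) hu[x, y, ] <- 50     # muscle analog ring
  }
  vol <- ctVolume(hu)
  params <- segmentationParams(minComponentVoxels = 1L)
  raw <- thresholdSegment(vol, params)
  expect_true(any(maskData(raw)[11, 11, ]))   # marrow passes the window
  cleaned <- cleanMask(raw, vol, params)
  expect_false(any(maskData(cleaned) & huData(vol) == 30))
  expect_true(all(maskData(cleaned) == (huData(vol) == 50)))
})

test_that("cleanup removes small components by the size rule", {
  hu <- array(-500, c(24, 24, 4))
  hu[4:13, 4:13, ] <- 50            # big muscle block: 400 voxels
  hu[18:19, 18:19, 2] <- 40         # 4-voxel speck, isolated in one slice
  vol <- ctVolume(hu)
  cleaned <- cleanMask(thresholdSegment(vol), vol,
                       segmentationParams(minComponentVoxels = 50L))
  expect_false(any(maskData(cleaned)[18:19, 18:19, ]))
  expect_true(all(maskData(cleaned)[4:13, 4:13, ]))
})

test_that("cleaned masks are subsets of raw and recover phantom muscle", {
  g <- generatePhantom(smallSpec(seed = 33L), subjectRecord("S1", "severe"),
                       withTruth = TRUE)
  params <- segmentationParams()
  raw <- thresholdSegment(g$volume, params)
  cleaned <- cleanMask(raw, g$volume, params)
  expect_true(all(maskData(cleaned) <= maskData(raw)))   # subset chain
  # all retained voxels inside the HU window
  expect_true(all(huData(g$volume)[maskData(cleaned)] >= -10))
  expect_true(all(huData(g$volume)[maskData(cleaned)] <= 100))
  # covers >= 95% of true muscle, Dice >= 0.95
  tp <- sum(maskData(cleaned) & g$muscle)
  expect_gt(tp / sum(g$muscle), 0.95)
  dice <- 2 * tp / (sum(maskData(cleaned)) + sum(g$muscle))
  expect_gt(dice, 0.95)
  # marrow and veins are gone
  expect_lt(mean(maskData(cleaned)[g$truth == 4]), 0.01)
  expect_lt(mean(maskData(cleaned)[g$truth == 6]), 0.01)
})

test_that("restrictZ clears slices outside the interval and validates it", {
  hu <- array(50, c(6, 6, 10))
  vol <- ctVolume(hu)
  m <- thresholdSegment(vol)
  expect_identical(maskData(restrictZ(m, 1, 10)), maskData(m))  # identity
  half <- restrictZ(m, 1, 5)
  expect_equal(sum(maskData(half)), sum(maskData(m)) / 2)
  expect_true(all(maskData(half) <= maskData(m)))  # subset property
  expect_equal(zRange(half), c(1L, 5L))
  expect_error(restrictZ(m, 6, 5), "inverted")
  expect_error(restrictZ(m, 0, 5), "outside")
})

test_that("an all-out-of-window volume yields a 'no muscle found' error", {
  vol <- ctVolume(array(-500, c(8, 8, 4)))
  expect_error(cleanMask(thresholdSegment(vol), vol), "no muscle found")
})
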