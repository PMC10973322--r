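test_that("noise-free constant-HU phantom paints every muscle voxel with that value", {
  tp <- defaultTissueParams()
  tp$muscle_mild <- c(mean = 45, sd = 0)
  spec <- smallSpec(seed = 3L, tissueParams = tp, imfFraction = 0,
                    noiseSD = 0)
  g <- generatePhantom(spec, subjectRecord("S1", "mild"), withTruth = TRUE)
  expect_true(all(huData(g$volume)[g$muscle] == 45))
})

test_that("muscle voxel HU reproduce the configured group distributions", {
  # >= 1e4 muscle voxels; mean within 3 standard errors (and the
  # documented 44.6 +/- 0.5 band), SD on target
  spec <- phantomSpec(seed = 42L, imfFraction = 0, distalGradient = 0)
  for (grp in c("mild", "severe")) {
    g <- generatePhantom(spec, subjectRecord("X1", grp), withTruth = TRUE)
    hu <- huData(g$volume)[g$muscle]
    expect_gt(length(hu), 1e4)
    p <- spec@tissueParams[[paste0("muscle_", grp)]]
    se <- p[["sd"]] / sqrt(length(hu))
    expect_lt(abs(mean(hu) - p[["mean"]]), max(3 * se, 0.5))
    expect_lt(abs(sd(hu) - p[["sd"]]), 3 * p[["sd"]] / sqrt(2 * length(hu)) + 0.1)
  }
})

test_that("phantom generation is deterministic in (seed, subject) and varies with both", {
  spec <- smallSpec(seed = 9L)
  rec <- subjectRecord("S1", "mild")
  v1 <- generatePhantom(spec, rec)
  v2 <- generatePhantom(spec, rec)
  expect_identical(huData(v1), huData(v2))
  v3 <- generatePhantom(spec, subjectRecord("S2", "mild"))
  expect_false(identical(huData(v1), huData(v3)))
  spec2 <- smallSpec(seed = 10L)
  expect_false(identical(huData(v1), huData(generatePhantom(spec2, rec))))
})

test_that("undersized grids fail naming the offending structure", {
  spec <- phantomSpec(gridShape = c(12L, 12L, 8L), seed = 1L)
  expect_error(generatePhantom(spec, subjectRecord("S1", "mild")),
               "has no voxels")
})

test_that("severe subjects get the distal HU offset, peaking in the fourth fifth", {
  tp <- defaultTissueParams()
  tp$muscle_severe <- c(mean = 40, sd = 0)
  spec <- phantomSpec(gridShape = c(64L, 64L, 60L), seed = 2L,
                      tissueParams = tp, imfFraction = 0,
                      distalGradient = -4)
  g <- generatePhantom(spec, subjectRecord("S1", "severe"),
                       withTruth = TRUE)
  hu <- huData(g$volume)
  sliceMean <- vapply(1:60, function(z) {
    sel <- g$muscle[, , z]
    mean(hu[, , z][sel])
  }, 0)
  segMean <- tapply(sliceMean, rep(1:5, each = 12), mean)
  expect_equal(unname(which.min(segMean)), 4)   # most negative offset
  expect_lt(max(abs(sliceMean - 40)), 4 + 0.51) # bounded by the gradient
  # mild subjects are unaffected
  tp$muscle_mild <- c(mean = 45, sd = 0)
  spec2 <- phantomSpec(gridShape = c(64L, 64L, 60L), seed = 2L,
                       tissueParams = tp, imfFraction = 0,
                       distalGradient = -4)
  gm <- generatePhantom(spec2, subjectRecord("S1", "mild"),
                        withTruth = TRUE)
  expect_true(all(huData(gm$volume)[gm$muscle] == 45))
})

test_that("runoff score sampling respects the dichotomisation boundary and group means", {
  for (i in 1:50)
    expect_lte(sampleRunoffScores("mild", seed = i)[["dsa_score"]], 7)
  for (i in 1:50)
    expect_gt(sampleRunoffScores("severe", seed = i)[["dsa_score"]], 7)
  # zero-SD draw collapses to the group mean
  d <- sampleRunoffScores("mild", seed = 1L, dsaSD = 0, ctaSD = 0)
  expect_equal(d[["dsa_score"]], 3.3)
  # Monte-Carlo mean of the truncated severe sampler
  set.seed(99)
  draws <- replicate(1e4, sampleRunoffScores("severe")[["dsa_score"]])
  expect_lt(abs(mean(draws) - 12.3), 0.3)
})

test_that("cohorts have the right size, labels, CSV, and are seed-deterministic", {
  spec <- smallSpec(seed = 7L)
  d1 <- withr::local_tempdir()
  c1 <- generateCohort(4L, 3L, spec, seed = 7L, outDir = d1)
  expect_equal(nrow(c1$subjects), 7)
  expect_equal(sum(c1$subjects$group == "mild"), 4)
  expect_equal(length(c1$volumes), 7)
  expect_true(all(file.exists(unlist(c1$volumes))))
  expect_identical(dichotomize(c1$subjects$dsa_score), c1$subjects$group)

  d2 <- withr::local_tempdir()
  generateCohort(4L, 3L, spec, seed = 7L, outDir = d2)
  expect_identical(readLines(file.path(d1, "subjects.csv")),
                   readLines(file.path(d2, "subjects.csv")))

  c3 <- generateCohort(1L, 1L, spec, seed = 1L)
  expect_setequal(c3$subjects$group, c("mild", "severe"))
})

test_that("cohorts separate the groups on mean muscle HU", {
  spec <- smallSpec(seed = 0L)
  ok <- vapply(1:8, function(r) {
    co <- generateCohort(36L, 20L, spec, seed = 100L + r,
                         withTruth = TRUE)
    mu <- vapply(seq_along(co$volumes), function(i)
      mean(huData(co$volumes[[i]])[co$muscle[[i]]]), 0)
    mean(mu[co$subjects$group == "mild"]) >
      mean(mu[co$subjects$group == "severe"])
  }, TRUE)
  expect_true(all(ok))
})
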