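test_that("z partition is equal-length with proximal-first remainders", {
  p50 <- subsetPartition(c(1L, 50L), 5)
  expect_equal(p50[, "end"] - p50[, "start"] + 1L, rep(10L, 5))
  p52 <- subsetPartition(c(1L, 52L), 5)
  expect_equal(p52[, "end"] - p52[, "start"] + 1L, c(11L, 11L, 10L, 10L, 10L))
  expect_equal(unname(p52[1, "start"]), 1L)
  expect_equal(unname(p52[5, "end"]), 52L)
  expect_error(subsetPartition(c(1L, 4L), 5), "shorter")
})

test_that("splitZ yields a disjoint cover of the input mask", {
  set.seed(61)
  for (r in 1:5) {
    m <- array(runif(10 * 10 * 23) < 0.4, c(10, 10, 23))
    m[, , sample(23, 3)] <- FALSE  # some empty slices
    mask <- muscleMask(m)
    segs <- splitZ(mask, 5)
    tot <- Reduce(`+`, lapply(segs, function(s) maskData(s) * 1L))
    expect_true(all(tot <= 1))                      # pairwise disjoint
    expect_identical(tot == 1, maskData(mask))      # union is the input
    for (s in segs) expect_true(all(maskData(s) <= maskData(mask)))
  }
})

test_that("k = 1 subset evaluation reproduces the whole-leg result exactly", {
  g <- generatePhantom(smallSpec(seed = 71L), subjectRecord("S1", "mild"),
                       withTruth = TRUE)
  co <- generateCohort(6L, 6L, smallSpec(seed = 71L), seed = 71L)
  masks <- lapply(co$volumes, segmentMuscle)
  feats <- t(vapply(seq_along(co$volumes), function(i)
    extractFeatures(co$volumes[[i]], masks[[i]],
                    features = c("histogram_10Percentile",
                                 "gldm_DependenceNonUniformityNormalized")),
    numeric(2)))
  colnames(feats) <- c("histogram_10Percentile",
                       "gldm_DependenceNonUniformityNormalized")
  transform <- zscoreFit(feats)
  Z <- zscoreApply(feats, transform)
  y <- as.integer(co$subjects$group == "severe")
  whole <- predictPublished(Z, variant = "LRM-I")
  wholeRoc <- rocAnalysis(whole$probability, y)

  sub1 <- evaluateSubsets(co$volumes, masks, co$subjects$group,
                          list(`LRM-I` = publishedModel("LRM-I")),
                          k = 1L, transform = transform)
  expect_identical(sub1$auc, wholeRoc$auc)
  m <- muscleCTA:::.fixedCutoffMetrics(whole$probability, y, 0.35)
  expect_identical(sub1$sensitivity, m$sensitivity)
  expect_identical(sub1$specificity, m$specificity)
  expect_identical(sub1$accuracy, m$accuracy)
})

test_that("published cutoffs are reused unchanged across segments", {
  co <- generateCohort(4L, 4L, smallSpec(seed = 72L), seed = 72L)
  masks <- lapply(co$volumes, segmentMuscle)
  feats <- t(vapply(seq_along(co$volumes), function(i)
    extractFeatures(co$volumes[[i]], masks[[i]],
                    features = c("histogram_10Percentile",
                                 "gldm_DependenceNonUniformityNormalized")),
    numeric(2)))
  colnames(feats) <- c("histogram_10Percentile",
                       "gldm_DependenceNonUniformityNormalized")
  transform <- zscoreFit(feats)
  ctaZ <- as.numeric(scale(co$subjects$cta_score))
  res <- evaluateSubsets(co$volumes, masks, co$subjects$group,
                         list(`LRM-I` = publishedModel("LRM-I"),
                              `LRM-II` = publishedModel("LRM-II")),
                         k = 4L, transform = transform, ctaZ = ctaZ)
  expect_equal(nrow(res), 8)
  expect_true(all(res$cutoff[res$model == "LRM-I"] == 0.35))
  expect_true(all(res$cutoff[res$model == "LRM-II"] == 0.43))
  expect_true(all(res$n == 8))
})

test_that("subjects with an empty segment are excluded with a warning", {
  co <- generateCohort(3L, 3L, smallSpec(seed = 73L), seed = 73L)
  masks <- lapply(co$volumes, segmentMuscle)
  # empty one subject's distal half so its last segments are empty
  m <- maskData(masks[[1]])
  m[, , 9:16] <- FALSE
  masks[[1]] <- muscleMask(m, spacing = voxelSpacing(masks[[1]]))
  feats <- matrix(vapply(seq_along(co$volumes), function(i)
    extractFeatures(co$volumes[[i]], segmentMuscle(co$volumes[[i]]),
                    features = "histogram_10Percentile"), numeric(1)),
    ncol = 1, dimnames = list(NULL, "histogram_10Percentile"))
  transform <- zscoreFit(feats)
  mod <- publishedModel("LRM-I")
  mod$coefficients <- mod$coefficients["histogram_10Percentile"]
  expect_warning(
    res <- evaluateSubsets(co$volumes, masks, co$subjects$group,
                           list(m = mod), k = 8L, transform = transform),
    "excluded")
  expect_true(any(res$n < 6))
})
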