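test_that("LASSO reaches the least-squares fit as the penalty vanishes", {
  set.seed(41)
  n <- 80
  X <- zscore(matrix(rnorm(n * 3), n,
                     dimnames = list(NULL, c("a", "b", "c"))))$X
  y <- rbinom(n, 1, plogis(X[, 1]))
  fit <- glmnet::glmnet(X, y, family = "gaussian", standardize = FALSE,
                        lambda = c(0.5, 0.1, 0.01, 0), thresh = 1e-14)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(as.numeric(coef(fit, s = 0))), unname(ols),
               tolerance = 1e-6)
})

test_that("the KKT threshold zeroes every LASSO coefficient", {
  set.seed(42)
  n <- 56
  X <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("x", 1:8)))
  X <- zscore(X)$X
  y <- rbinom(n, 1, 0.4)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / n
  res <- lassoSelect(X, y, folds = 5, seed = 1)
  beta <- res$coef_path[, res$lambda >= lmax, drop = FALSE]
  expect_true(all(beta == 0))
  # and the path's largest lambda is the first with all-zero coefficients
  expect_lt(max(res$lambda) - lmax, 1e-8)
})

test_that("LASSO recovers informative columns among noise", {
  set.seed(43)
  groups <- rep(0:1, c(36, 20))
  hits <- replicate(20, {
    X <- matrix(rnorm(56 * 45), 56,
                dimnames = list(NULL, paste0("f", 1:45)))
    X[, 1:5] <- X[, 1:5] + 1.2 * groups
    Z <- zscore(X)$X
    sel <- lassoSelect(Z, groups, folds = 10)$selected
    all(paste0("f", 1:5) %in% sel)
  })
  expect_gt(mean(hits), 0.8)
})

test_that("selection shrinks weakly as lambda grows", {
  set.seed(44)
  X <- zscore(matrix(rnorm(60 * 10), 60,
                     dimnames = list(NULL, paste0("x", 1:10))))$X
  y <- rbinom(60, 1, plogis(X[, 1] - X[, 2]))
  res <- lassoSelect(X, y, folds = 5, seed = 2)
  nActive <- colSums(res$coef_path != 0)  # columns ordered by decreasing lambda
  expect_true(all(diff(rev(nActive)) <= 1 + ncol(X)))  # finite, defined
  expect_equal(unname(nActive[1]), 0)  # all zero at the largest lambda
})

test_that("logistic fit recovers generating parameters and the OR arithmetic", {
  set.seed(45)
  n <- 5000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1 + 2 * x))
  fit <- fitLogistic(cbind(x = x), y)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 1), 3 * fit$se[1])
  expect_lt(abs(fit$coefficients[["x"]] - 2), 3 * fit$se[2])
  expect_lt(fit$omnibus_p, 1e-10)
  expect_gt(fit$hosmer_lemeshow_p, 0.001)
  # OR = exp(coef); CI = exp(coef +/- 1.96 SE) exactly
  expect_equal(fit$or, exp(fit$coefficients))
  expect_equal(fit$or_ci[, "lower"], exp(fit$coefficients - 1.96 * fit$se))
  expect_equal(fit$or_ci[, "upper"], exp(fit$coefficients + 1.96 * fit$se))
  expect_equal(round(exp(-1.29), 2), 0.28)  # reported coefficient -> OR
})

test_that("null model on balanced outcome has a near-zero constant", {
  set.seed(46)
  y <- rep(0:1, 50)
  fit <- fitLogistic(cbind(x = rnorm(100)), y)
  expect_lt(abs(fit$coefficients[["(Intercept)"]]), 0.5)
  expect_gt(fit$omnibus_p, 0.01)
})

test_that("perfect separation is detected and reported", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(0:1, each = 20)
  expect_error(fitLogistic(cbind(x = x), y), "separation")
  expect_warning(fit <- fitLogistic(cbind(x = x), y, onSeparation = "warn"),
                 "separation")
  expect_true(fit$separation)
})

test_that("ROC analysis matches the pair-counting oracle and trivial cases", {
  # perfect scores
  r <- rocAnalysis(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # worked example: frozen against the exhaustive pair-count oracle
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 1, 0, 0, 1)
  want <- oracleAuc(scores, labels)
  expect_equal(want, 6 / 8)
  expect_equal(rocAnalysis(scores, labels)$auc, want)

  # random scores on many subjects: AUC near 1/2
  set.seed(47)
  r0 <- rocAnalysis(runif(2000), rbinom(2000, 1, 0.4))
  expect_lt(abs(r0$auc - 0.5), 0.03)
  expect_gt(r0$auc_p, 1e-4)

  # ties handled as half-concordant
  expect_equal(rocAnalysis(c(1, 1, 1, 1), c(0, 1, 0, 1))$auc, 0.5)
})

test_that("the Youden cutoff is maximal and ties break toward sensitivity", {
  set.seed(48)
  scores <- round(rnorm(80), 1)
  y <- rbinom(80, 1, plogis(2 * scores))
  r <- rocAnalysis(scores, y)
  youdenAt <- function(cut) {
    sens <- mean(scores[y == 1] >= cut)
    spec <- mean(scores[y == 0] < cut)
    sens + spec - 1
  }
  cand <- c(min(scores) - 1, sort(unique(scores)),
            (head(sort(unique(scores)), -1) +
               tail(sort(unique(scores)), -1)) / 2)
  expect_gte(youdenAt(r$cutoff) + 1e-12, max(vapply(cand, youdenAt, 0)))
  # lower cutoff preferred on ties: shifting down to the next candidate
  # must strictly reduce the Youden index or not be a candidate
  expect_equal(youdenAt(r$cutoff), r$youden)
})

test_that("published models reproduce the reported equations", {
  z0 <- c(histogram_10Percentile = 0,
          gldm_DependenceNonUniformityNormalized = 0)
  expect_equal(predictPublished(z0, variant = "LRM-I")$logit, -0.85)
  expect_equal(predictPublished(z0, ctaZ = 0, variant = "LRM-II")$logit,
               -0.90)
  z1 <- c(histogram_10Percentile = 1,
          gldm_DependenceNonUniformityNormalized = 1)
  p1 <- predictPublished(z1, variant = "LRM-I")
  expect_equal(p1$logit, -1.29 - 0.67 - 0.85)
  expect_equal(p1$probability, 1 / (1 + exp(2.81)))
  expect_equal(unname(p1$class), "mild")
  expect_error(predictPublished(c(histogram_10Percentile = 0),
                                variant = "LRM-I"), "missing")
  expect_error(predictPublished(z0, variant = "LRM-II"), "CTA")
  # classification flips exactly at the published cutoff
  m <- publishedModel("LRM-I")
  zc <- qlogis(m$cutoff)
  f1 <- (zc - m$constant) / m$coefficients[["histogram_10Percentile"]]
  atCut <- predictPublished(c(histogram_10Percentile = f1,
                              gldm_DependenceNonUniformityNormalized = 0),
                            variant = "LRM-I")
  expect_equal(unname(atCut$class), "severe")  # >= cutoff is severe
})

test_that("buildModels is deterministic and degrades under label shuffling", {
  set.seed(49)
  groups <- rep(c("mild", "severe"), c(36, 20))
  X <- matrix(rnorm(56 * 20), 56, dimnames = list(NULL, paste0("f", 1:20)))
  X[, 1] <- X[, 1] - 1.5 * (groups == "severe")
  X[, 2] <- X[, 2] - 1.0 * (groups == "severe")
  Z <- zscore(X)$X
  cta <- rnorm(56, 6, 3) + 6 * (groups == "severe")

  m1 <- buildModels(Z, cta, groups, seed = 7)
  m2 <- buildModels(Z, cta, groups, seed = 7)
  expect_identical(m1$lrm1$coefficients, m2$lrm1$coefficients)
  expect_identical(m1$lrm2$roc$auc, m2$lrm2$roc$auc)
  expect_gt(m1$lrm1$roc$auc, 0.75)

  # shuffled labels: the CTA baseline collapses to chance and the fitted
  # models lose most of their apparent discrimination
  set.seed(50)
  sh <- sample(groups)
  ms <- buildModels(Z, cta, sh, seed = 7, onSeparation = "warn")
  expect_lt(abs(ms$cta$auc - 0.5), 0.12)
  expect_lt(ms$lrm1$roc$auc, m1$lrm1$roc$auc)
})
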