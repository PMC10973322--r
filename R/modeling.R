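## LASSO feature selection, logistic regression with diagnostics,
## ROC/Youden evaluation, and the published fixed-coefficient models.

#' LASSO feature selection with stratified cross-validation
#'
#' Linear-response LASSO (squared-error loss on the 0/1 outcome, the MSE
#' criterion) solved by coordinate descent (glmnet) over a log-spaced
#' lambda grid, with outcome-stratified k-fold cross-validation.  The
#' selected lambda minimises the mean CV MSE.  A logistic-deviance LASSO
#' is available via `loss = "deviance"`.
#'
#' @param X Standardised numeric matrix (subjects x features).
#' @param y Binary outcome (0/1, logical, or two-level factor where the
#'   second level is the event).
#' @param folds Number of CV folds (default 10; must not exceed n).
#' @param seed Optional seed for the fold assignment.
#' @param loss `"mse"` (default) or `"deviance"`.
#' @return A list of class `LassoResult`: `lambda` (descending grid),
#'   `cv_mse_mean`, `cv_mse_sd`, `lambda_star`, `coef_path` (features x
#'   lambda), `selected` (names with non-zero weight at `lambda_star`),
#'   and `fit` (the underlying glmnet objects).
#' @export
lassoSelect <- function(X, y, folds = 10L, seed = NULL, loss = "mse") {
  X <- as.matrix(X)
  y <- .binaryOutcome(y)
  loss <- match.arg(loss, c("mse", "deviance"))
  n <- nrow(X)
  if (length(unique(y)) < 2) stop("constant outcome")
  if (n < folds) stop("need at least as many subjects as folds")
  if (!is.null(seed)) set.seed(as.integer(seed))

  # outcome-stratified fold assignment
  foldid <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }

  family <- if (loss == "mse") "gaussian" else "binomial"
  cv <- glmnet::cv.glmnet(X, y, family = family, foldid = foldid,
                          standardize = FALSE,
                          type.measure = if (loss == "mse") "mse" else
                            "deviance")
  beta <- as.matrix(cv$glmnet.fit$beta)
  sel <- rownames(beta)[beta[, which(cv$lambda == cv$lambda.min)[1]] != 0]
  structure(list(
    lambda = cv$lambda, cv_mse_mean = cv$cvm, cv_mse_sd = cv$cvsd,
    lambda_star = cv$lambda.min, coef_path = beta, selected = sel,
    foldid = foldid, fit = cv
  ), class = "LassoResult")
}

.binaryOutcome <- function(y) {
  if (is.factor(y)) as.integer(y) - 1L
  else if (is.logical(y)) as.integer(y)
  else if (is.character(y)) as.integer(factor(y)) - 1L
  else {
    stopifnot(all(y %in% c(0, 1)))
    as.integer(y)
  }
}

#' @export
print.LassoResult <- function(x, ...) {
  cat("LassoResult: lambda* =", signif(x$lambda_star, 3),
      "(min CV MSE", signif(min(x$cv_mse_mean), 3), ")\n")
  cat("  selected:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

# Hosmer-Lemeshow goodness of fit with g groups by predicted-probability
# deciles; ties split by stable sort.
.hosmerLemeshow <- function(p, y, g = 10L) {
  n <- length(p)
  ord <- order(p)  # stable
  grp <- rep(seq_len(g), each = ceiling(n / g), length.out = n)[
    order(ord)]  # map back to original positions
  obs <- tapply(y, grp, sum)
  exp <- tapply(p, grp, sum)
  size <- tabulate(grp)
  keep <- size > 0
  stat <- sum((obs[keep] - exp[keep])^2 /
                (exp[keep] * (1 - exp[keep] / size[keep])))
  df <- sum(keep) - 2
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE))
}

#' Fit a logistic regression model with diagnostics
#'
#' Maximum-likelihood fit with Wald standard errors, odds ratios with
#' 95% Wald intervals (`exp(coef +/- 1.96 SE)`), a likelihood-ratio
#' omnibus test against the intercept-only model, and the
#' Hosmer-Lemeshow test with 10 decile groups.
#'
#' @param X Numeric matrix of predictors (subjects x variables).
#' @param y Binary outcome (event = 1, see [lassoSelect()]).
#' @param onSeparation `"error"` (default) to fail on perfect separation
#'   with a hint toward penalisation, or `"warn"` to return the
#'   (degenerate) fit flagged.
#' @return A list of class `ModelReport`: `variables`, `coefficients`
#'   (including the constant), `se`, `or`, `or_ci`, `p`, `omnibus_p`,
#'   `hosmer_lemeshow_p`, `separation`, `fitted`, and `roc` (`NULL`
#'   until [rocAnalysis()] output is attached).
#' @export
fitLogistic <- function(X, y, onSeparation = "error") {
  X <- as.matrix(X)
  y <- .binaryOutcome(y)
  onSeparation <- match.arg(onSeparation, c("error", "warn"))
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  separated <- fit$deviance < 1e-6
  if (separated) {
    msg <- "perfect separation detected; consider a penalized fit"
    if (onSeparation == "error") stop(msg) else warning(msg)
  }
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- cf / se
  pvals <- 2 * pnorm(-abs(z))
  orLo <- exp(cf - 1.96 * se)
  orHi <- exp(cf + 1.96 * se)
  omnibus <- pchisq(fit$null.deviance - fit$deviance,
                    df = length(cf) - 1, lower.tail = FALSE)
  hl <- .hosmerLemeshow(fitted(fit), y)
  structure(list(
    variables = colnames(X),
    coefficients = cf, se = se, or = exp(cf),
    or_ci = cbind(lower = orLo, upper = orHi), p = pvals,
    omnibus_p = omnibus, hosmer_lemeshow_p = hl$p,
    separation = separated, fitted = unname(fitted(fit)),
    glm = fit, roc = NULL
  ), class = "ModelReport")
}

#' @export
print.ModelReport <- function(x, ...) {
  cat("ModelReport:", length(x$variables), "variable(s)\n")
  tab <- data.frame(coef = x$coefficients, OR = x$or,
                    lo = x$or_ci[, 1], hi = x$or_ci[, 2], p = x$p)
  print(signif(as.matrix(tab), 3))
  cat(sprintf("  omnibus p = %.3g, Hosmer-Lemeshow p = %.3g\n",
              x$omnibus_p, x$hosmer_lemeshow_p))
  if (!is.null(x$roc))
    cat(sprintf("  AUC %.3f (%.3f, %.3f), cutoff %.3g\n", x$roc$auc,
                x$roc$auc_ci[1], x$roc$auc_ci[2], x$roc$cutoff))
  invisible(x)
}

# sensitivity/specificity/accuracy at a fixed cutoff (predict event iff
# score >= cutoff), with the classification counts alongside the rates
.fixedCutoffMetrics <- function(scores, y, cutoff) {
  pred <- scores >= cutoff
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0); fp <- sum(pred & y == 0)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(y),
       counts = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

#' ROC analysis with DeLong CI and Youden cutoff
#'
#' Empirical ROC: the AUC is the Mann-Whitney probability (ties count
#' 1/2, equivalent to trapezoidal integration), the 95% CI and the test
#' against AUC = 0.5 use DeLong's variance, and the reported cutoff
#' maximises the Youden index (sensitivity + specificity - 1) over
#' midpoints between consecutive observed scores, ties resolved toward
#' the lower (more sensitive) cutoff.  A subject is called positive when
#' its score is at or above the cutoff.
#'
#' @param scores Numeric predictor (higher = more likely event).
#' @param labels Binary outcome (event = 1, see [lassoSelect()]).
#' @return List with `auc`, `auc_ci`, `auc_var`, `auc_p`, `cutoff`,
#'   `sensitivity`, `specificity`, `accuracy`, `counts`, `youden`.
#' @export
rocAnalysis <- function(scores, labels) {
  y <- .binaryOutcome(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  pos <- scores[y == 1]
  neg <- scores[y == 0]

  # Mann-Whitney AUC with tie correction
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)

  rocObj <- pROC::roc(response = y, predictor = scores,
                      levels = c(0, 1), direction = "<", quiet = TRUE)
  # pROC warns that a degenerate (AUC = 1) curve has zero variance; the
  # value itself is what the report needs
  aucVar <- suppressWarnings(pROC::var(rocObj, method = "delong"))
  ci <- as.numeric(suppressWarnings(
    pROC::ci.auc(rocObj, method = "delong")))[c(1, 3)]
  aucP <- 2 * pnorm(-abs((auc - 0.5) / sqrt(aucVar)))

  u <- sort(unique(scores))
  cand <- if (length(u) > 1)
    c(u[1] - 1, (u[-1] + u[-length(u)]) / 2) else u[1]
  youden <- vapply(cand, function(cut) {
    m <- .fixedCutoffMetrics(scores, y, cut)
    m$sensitivity + m$specificity - 1
  }, 0)
  cutoff <- cand[which.max(youden)]  # lowest candidate on ties
  m <- .fixedCutoffMetrics(scores, y, cutoff)

  c(list(auc = auc, auc_ci = ci, auc_var = aucVar, auc_p = aucP,
         cutoff = cutoff, youden = max(youden)), m)
}

#' Published fixed-coefficient logistic models
#'
#' The two reported models of PAD severity (severe = DSA runoff score
#' > 7), with immutable coefficients on z-scored inputs:
#' LRM-I `logit(P) = -1.29 f1 - 0.67 f2 - 0.85` and LRM-II
#' `logit(P) = 1.18 CTA - 1.11 f1 - 0.68 f2 - 0.90`, where f1 is
#' `histogram_10Percentile`, f2 is
#' `gldm_DependenceNonUniformityNormalized` and CTA is the standardised
#' CTA runoff score.  Classification cutoffs on the probability scale are
#' 0.35 (LRM-I) and 0.43 (LRM-II).
#'
#' @param variant `"LRM-I"` or `"LRM-II"`.
#' @return List with `variant`, `constant`, `coefficients` (named),
#'   `cutoff`, and `usesCta`.
#' @export
publishedModel <- function(variant = c("LRM-I", "LRM-II")) {
  variant <- match.arg(variant)
  if (variant == "LRM-I") {
    list(variant = variant, constant = -0.85,
         coefficients = c(histogram_10Percentile = -1.29,
                          gldm_DependenceNonUniformityNormalized = -0.67),
         cutoff = 0.35, usesCta = FALSE)
  } else {
    list(variant = variant, constant = -0.90,
         coefficients = c(cta_score = 1.18,
                          histogram_10Percentile = -1.11,
                          gldm_DependenceNonUniformityNormalized = -0.68),
         cutoff = 0.43, usesCta = TRUE)
  }
}

#' Predict PAD severity with a published model
#'
#' @param features Named numeric vector or matrix (subjects x features)
#'   of z-scored values containing `histogram_10Percentile` and
#'   `gldm_DependenceNonUniformityNormalized`.
#' @param ctaZ Standardised CTA runoff score(s); required for LRM-II.
#' @param variant `"LRM-I"` or `"LRM-II"`.
#' @return List with `logit`, `probability`, and `class` (`"severe"` iff
#'   probability >= the published cutoff, else `"mild"`).
#' @examples
#' predictPublished(c(histogram_10Percentile = 0,
#'                    gldm_DependenceNonUniformityNormalized = 0))
#' @export
predictPublished <- function(features, ctaZ = NULL,
                             variant = c("LRM-I", "LRM-II")) {
  variant <- match.arg(variant)
  model <- publishedModel(variant)
  if (is.null(dim(features)))
    features <- matrix(features, 1, dimnames = list(NULL, names(features)))
  needed <- setdiff(names(model$coefficients), "cta_score")
  missing <- setdiff(needed, colnames(features))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  logit <- model$constant +
    as.numeric(features[, needed, drop = FALSE] %*%
                 model$coefficients[needed])
  if (model$usesCta) {
    if (is.null(ctaZ)) stop("LRM-II requires the standardised CTA score")
    logit <- logit + model$coefficients[["cta_score"]] * ctaZ
  }
  prob <- 1 / (1 + exp(-logit))
  list(logit = logit, probability = prob,
       class = ifelse(prob >= model$cutoff, "severe", "mild"))
}

# backward elimination on Wald p-values; 'protect' variables are never
# dropped; retains at least one variable
.backwardEliminate <- function(X, y, retainAlpha = 0.10, protect = character(),
                               onSeparation = "error") {
  vars <- colnames(X)
  repeat {
    fit <- fitLogistic(X[, vars, drop = FALSE], y,
                       onSeparation = onSeparation)
    p <- fit$p[-1]
    names(p) <- vars
    droppable <- setdiff(vars[p > retainAlpha], protect)
    if (!length(droppable) || length(vars) <= 1) return(fit)
    worst <- droppable[which.max(p[droppable])]
    vars <- setdiff(vars, worst)
  }
}

#' Build the two muscle-feature logistic models
#'
#' LASSO selection on the screened, standardised muscle features, then
#' LRM-I (selected features) and LRM-II (the same features plus the
#' standardised CTA score), so LRM-I is nested in LRM-II.  Optionally
#' (`refine = "backward"`) each model is pruned by backward elimination
#' on Wald p-values (retain p < `retainAlpha`; the CTA score is never
#' dropped from LRM-II) -- an interpretation of reference analyses whose
#' final tables omit some selected variables.  Both models and the CTA
#' score alone are evaluated by [rocAnalysis()].
#'
#' @param X Screened, standardised feature matrix.
#' @param ctaScore Raw CTA runoff scores (standardised internally).
#' @param groups `"mild"`/`"severe"` labels per row.
#' @param seed Seed for the CV fold assignment.
#' @param folds CV folds for [lassoSelect()].
#' @param refine `"none"` (default; keep every selected variable) or
#'   `"backward"`.
#' @param retainAlpha Retention threshold for backward elimination.
#' @param onSeparation Passed to [fitLogistic()].
#' @return List with `lrm1`, `lrm2` (ModelReports with `roc` attached),
#'   `cta` (ROC summary of the CTA score alone), `lasso`
#'   (the [lassoSelect()] result) and `selected`.
#' @export
buildModels <- function(X, ctaScore, groups, seed = NULL, folds = 10L,
                        refine = "none", retainAlpha = 0.10,
                        onSeparation = "error") {
  X <- as.matrix(X)
  refine <- match.arg(refine, c("none", "backward"))
  y <- as.integer(groups == "severe")
  lasso <- lassoSelect(X, y, folds = folds, seed = seed)
  selected <- lasso$selected
  if (!length(selected)) {
    # degenerate selection: keep the single feature most correlated with
    # the outcome so downstream stages remain defined
    selected <- colnames(X)[which.max(abs(cor(X, y)))]
  }

  ctaZ <- as.numeric(scale(ctaScore) * sqrt(length(ctaScore) /
                                              (length(ctaScore) - 1)))
  X1 <- X[, selected, drop = FALSE]
  X2 <- cbind(X1, cta_score = ctaZ)

  lrm1 <- if (refine == "backward")
    .backwardEliminate(X1, y, retainAlpha, onSeparation = onSeparation)
  else fitLogistic(X1, y, onSeparation = onSeparation)
  lrm2 <- if (refine == "backward")
    .backwardEliminate(X2, y, retainAlpha, protect = "cta_score",
                       onSeparation = onSeparation)
  else fitLogistic(X2, y, onSeparation = onSeparation)

  lrm1$roc <- rocAnalysis(lrm1$fitted, y)
  lrm2$roc <- rocAnalysis(lrm2$fitted, y)
  ctaRoc <- rocAnalysis(ctaScore, y)

  list(lrm1 = lrm1, lrm2 = lrm2, cta = ctaRoc, lasso = lasso,
       selected = selected)
}
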