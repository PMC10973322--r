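## Z-score standardisation and univariable screening.

#' Fit a z-score transform
#'
#' Column means and population SDs (n denominator), retained so the same
#' transform can be applied to new data (e.g. per-segment features are
#' standardised with the whole-leg parameters).
#'
#' @param X Numeric matrix or data.frame, subjects in rows.
#' @return List with `center` and `scale` (named numeric vectors).
#' @export
zscoreFit <- function(X) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2, center)^2))
  zero <- names(scale)[scale == 0]
  if (length(zero))
    stop("zero-SD column(s): ", paste(zero, collapse = ", "))
  list(center = center, scale = scale)
}

#' Apply a z-score transform
#'
#' @param X Numeric matrix or data.frame.
#' @param params Transform from [zscoreFit()].
#' @return Standardised matrix.
#' @export
zscoreApply <- function(X, params) {
  X <- as.matrix(X)
  nm <- colnames(X)
  missing <- setdiff(nm, names(params$center))
  if (length(missing))
    stop("no transform parameters for column(s): ",
         paste(missing, collapse = ", "))
  sweep(sweep(X, 2, params$center[nm]), 2, params$scale[nm], "/")
}

#' Z-score standardise a feature matrix
#'
#' @param X Numeric matrix, subjects in rows.
#' @return List with the standardised matrix `X` and the stored
#'   `center`/`scale` parameters.
#' @examples
#' zscore(cbind(a = c(1, 2, 3)))$X
#' @export
zscore <- function(X) {
  params <- zscoreFit(X)
  c(list(X = zscoreApply(X, params)), params)
}

.groupsToFactor <- function(groups) {
  f <- factor(groups)
  if (nlevels(f) != 2) stop("exactly two groups required")
  f
}

.isNormal <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3) return(FALSE)
  tryCatch(shapiro.test(x)$p.value > alpha, error = function(e) FALSE)
}

#' Univariable test of a continuous feature between two groups
#'
#' Student's two-sided equal-variance t test when both groups pass the
#' Shapiro-Wilk normality gate at `normAlpha`, otherwise the Mann-Whitney
#' U test (normal approximation with tie correction).  Degenerate input
#' (zero pooled variance) is reported with `p = 1` and flagged.
#'
#' @param values Numeric vector.
#' @param groups Two-level factor (each level needs >= 3 observations).
#' @param welch Use Welch's t instead of the classic equal-variance t.
#' @param normAlpha Level of the normality gate (default 0.05).
#' @return List with `statistic`, `p`, and `test` (which test ran).
#' @export
univariableTest <- function(values, groups, welch = FALSE,
                            normAlpha = 0.05) {
  f <- .groupsToFactor(groups)
  if (any(table(f) < 3)) stop("both groups need at least 3 subjects")
  xs <- split(as.numeric(values), f)
  if (var(values) == 0)
    return(list(statistic = NA_real_, p = 1, test = "degenerate"))
  if (.isNormal(xs[[1]], normAlpha) && .isNormal(xs[[2]], normAlpha)) {
    ht <- t.test(xs[[1]], xs[[2]], var.equal = !welch)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         test = if (welch) "welch_t" else "student_t")
  } else {
    ht <- suppressWarnings(wilcox.test(xs[[1]], xs[[2]], exact = FALSE,
                                       correct = TRUE))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         test = "mann_whitney")
  }
}

#' Test association in a 2 x k contingency table
#'
#' Fisher's exact test when the table is 2 x 2 with any expected count
#' below 5, otherwise Pearson's chi-squared without continuity
#' correction.
#'
#' @param table Matrix of non-negative integer counts, 2 rows.
#' @return List with `statistic`, `p`, and `test`.
#' @examples
#' categoricalTest(matrix(c(26, 10, 12, 8), 2))
#' @export
categoricalTest <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2, 2)) && any(expected < 5)) {
    ht <- fisher.test(tab)
    list(statistic = NA_real_, p = ht$p.value, test = "fisher")
  } else {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         test = "chisq")
  }
}

#' Univariable screening of a feature matrix
#'
#' Runs [univariableTest()] per feature and selects features with
#' `p < alpha`.  No multiple-testing correction is applied, matching the
#' p < 0.05 screening convention of the reference analysis.
#'
#' @param X Standardised feature matrix (subjects x features).
#' @param groups Two-level group labels per row.
#' @param alpha Selection level (default 0.05).
#' @param welch Passed to [univariableTest()].
#' @return A data.frame with one row per feature: `feature`, `family`,
#'   group means, `statistic`, `p`, `test`, `selected`.  The attribute
#'   `"selected"` holds the selected feature names.
#' @export
screenFeatures <- function(X, groups, alpha = 0.05, welch = FALSE) {
  X <- as.matrix(X)
  f <- .groupsToFactor(groups)
  lev <- levels(f)
  res <- lapply(colnames(X), function(nm) {
    ht <- univariableTest(X[, nm], f, welch = welch)
    mu <- tapply(X[, nm], f, mean)
    data.frame(feature = nm, family = sub("_.*$", "", nm),
               mean1 = mu[[1]], mean2 = mu[[2]],
               statistic = ht$statistic, p = ht$p, test = ht$test,
               selected = ht$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "mean1"] <- paste0("mean_", lev[1])
  names(out)[names(out) == "mean2"] <- paste0("mean_", lev[2])
  rownames(out) <- NULL
  attr(out, "selected") <- out$feature[out$selected]
  out
}
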