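## Five-segment sub-dataset analysis along the knee-to-ankle axis.

#' Partition a slice interval into k near-equal segments
#'
#' Segments are contiguous, disjoint, cover the interval exactly, and
#' differ in length by at most one slice; remainder slices are assigned
#' proximal-first (segment 1 is at the knee).
#'
#' @param zRange Integer length-2 inclusive slice interval.
#' @param k Number of segments (default 5).
#' @return Integer matrix `k x 2` of inclusive (start, end) slice indices.
#' @export
subsetPartition <- function(zRange, k = 5L) {
  len <- zRange[2] - zRange[1] + 1L
  if (len < k) stop("slice interval shorter than k")
  base <- len %/% k
  lens <- rep(base, k) + (seq_len(k) <= len %% k)
  ends <- zRange[1] - 1L + cumsum(lens)
  starts <- c(zRange[1], head(ends, -1) + 1L)
  cbind(start = as.integer(starts), end = as.integer(ends))
}

#' Split a muscle mask into k equal z-segments
#'
#' @param mask A [MuscleMask-class].
#' @param k Number of segments (default 5).
#' @return List of `k` [MuscleMask-class] objects ordered knee to ankle.
#' @export
splitZ <- function(mask, k = 5L) {
  stopifnot(is(mask, "MuscleMask"))
  part <- subsetPartition(zRange(mask), k)
  lapply(seq_len(k), function(i) restrictZ(mask, part[i, 1], part[i, 2]))
}

# normalise a trained ModelReport or publishedModel() to
# (intercept, coefficients, cutoff, usesCta)
.modelTerms <- function(model) {
  if (inherits(model, "ModelReport")) {
    cf <- model$coefficients
    coefs <- cf[setdiff(names(cf), c("(Intercept)", "cta_score"))]
    usesCta <- "cta_score" %in% names(cf)
    cutoff <- if (!is.null(model$roc)) model$roc$cutoff else
      stop("trained model has no ROC cutoff attached")
    list(intercept = unname(cf["(Intercept)"]), coefficients = coefs,
         cutoff = cutoff, usesCta = usesCta,
         ctaCoef = if (usesCta) cf[["cta_score"]] else 0)
  } else {
    list(intercept = model$constant,
         coefficients = model$coefficients[
           setdiff(names(model$coefficients), "cta_score")],
         cutoff = model$cutoff, usesCta = isTRUE(model$usesCta),
         ctaCoef = if (isTRUE(model$usesCta))
           model$coefficients[["cta_score"]] else 0)
  }
}

#' Evaluate models on k equal z-segments
#'
#' For each segment, the models' input features are re-extracted from
#' that segment only, standardised with the whole-leg transform
#' parameters, and pushed through each model's fixed linear predictor;
#' classification uses each model's fixed whole-leg cutoff (cutoffs are
#' never re-optimised per segment).  Subjects with an empty segment mask
#' are excluded with a warning and listed in the `excluded` attribute.
#'
#' @param volumes List of [CTVolume-class] objects (one per subject).
#' @param masks List of whole-leg [MuscleMask-class] objects.
#' @param groups `"mild"`/`"severe"` label per subject.
#' @param models Named list of trained `ModelReport`s (with ROC attached)
#'   and/or [publishedModel()] objects.
#' @param k Number of segments (default 5).
#' @param disc A [DiscretizationParams-class].
#' @param transform Whole-leg z-score parameters from [zscoreFit()],
#'   covering every model feature.
#' @param ctaZ Standardised CTA score per subject (required if any model
#'   uses it).
#' @return A data.frame with one row per (segment, model): `subset`,
#'   `model`, `auc`, `auc_lo`, `auc_hi`, `auc_p`, `sensitivity`,
#'   `specificity`, `accuracy`, `cutoff`, `n`.
#' @export
evaluateSubsets <- function(volumes, masks, groups, models, k = 5L,
                            disc = discretizationParams(),
                            transform = NULL, ctaZ = NULL) {
  stopifnot(length(volumes) == length(masks),
            length(volumes) == length(groups))
  terms <- lapply(models, .modelTerms)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("'models' must be a named list")
  featNames <- unique(unlist(lapply(terms, function(t)
    names(t$coefficients))))
  if (is.null(transform))
    stop("whole-leg z-score 'transform' parameters are required")
  if (any(vapply(terms, `[[`, TRUE, "usesCta")) && is.null(ctaZ))
    stop("a model uses the CTA score: supply 'ctaZ'")
  y <- as.integer(groups == "severe")
  n <- length(volumes)

  # per-subject, per-segment feature extraction
  featArr <- array(NA_real_, c(n, k, length(featNames)),
                   dimnames = list(NULL, NULL, featNames))
  excluded <- character()
  for (s in seq_len(n)) {
    segs <- splitZ(masks[[s]], k)
    for (g in seq_len(k)) {
      if (!any(maskData(segs[[g]]))) {
        excluded <- c(excluded, sprintf("subject %d: empty segment %d",
                                        s, g))
        next
      }
      featArr[s, g, ] <- extractFeatures(volumes[[s]], segs[[g]], disc,
                                         features = featNames)
    }
  }
  if (length(excluded))
    warning("excluded: ", paste(excluded, collapse = "; "))

  rows <- list()
  for (g in seq_len(k)) {
    Fg <- matrix(featArr[, g, ], n, length(featNames),
                 dimnames = list(NULL, featNames))
    ok <- complete.cases(Fg)
    Z <- zscoreApply(Fg[ok, , drop = FALSE], transform)
    for (mn in names(models)) {
      t <- terms[[mn]]
      logit <- t$intercept +
        as.numeric(Z[, names(t$coefficients), drop = FALSE] %*%
                     t$coefficients)
      if (t$usesCta) logit <- logit + t$ctaCoef * ctaZ[ok]
      prob <- 1 / (1 + exp(-logit))
      roc <- rocAnalysis(prob, y[ok])
      m <- .fixedCutoffMetrics(prob, y[ok], t$cutoff)
      rows[[length(rows) + 1]] <- data.frame(
        subset = g, model = mn, auc = roc$auc,
        auc_lo = roc$auc_ci[1], auc_hi = roc$auc_ci[2],
        auc_p = roc$auc_p, sensitivity = m$sensitivity,
        specificity = m$specificity, accuracy = m$accuracy,
        cutoff = t$cutoff, n = sum(ok), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
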