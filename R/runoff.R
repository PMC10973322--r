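## Modified SVS runoff scoring, severity dichotomisation, and
## reader-agreement ICC.

#' Default modified SVS runoff rubric
#'
#' Six lower-leg artery segments graded 0-3 (patent to occluded) plus a
#' pedal-arch segment graded 0-1, each with weight 1 and no offset: the
#' attainable total is exactly 0-19.  The rubric is fully configurable
#' because published variants differ in segment tables and weights.
#'
#' @return A list with `segments` (data.frame: `segment`, `max_grade`,
#'   `weight`) and `offset`.
#' @export
defaultRubric <- function() {
  list(
    segments = data.frame(
      segment = c("popliteal", "tibioperoneal_trunk", "anterior_tibial",
                  "posterior_tibial", "peroneal", "dorsalis_pedis",
                  "pedal_arch"),
      max_grade = c(3L, 3L, 3L, 3L, 3L, 3L, 1L),
      weight = rep(1, 7),
      stringsAsFactors = FALSE
    ),
    offset = 0
  )
}

#' Compute a runoff score from per-segment stenosis grades
#'
#' `sum(weight * grade) + offset` over the rubric's segments.  Higher
#' scores indicate more severe disease; the default rubric spans 0-19.
#'
#' @param grades Named vector mapping every rubric segment to an integer
#'   grade within `0..max_grade`.
#' @param rubric A rubric as returned by [defaultRubric()].
#' @return The numeric runoff score.
#' @examples
#' g <- setNames(rep(0, 7), defaultRubric()$segments$segment)
#' runoffScore(g)  # 0
#' @export
runoffScore <- function(grades, rubric = defaultRubric()) {
  seg <- rubric$segments
  unknown <- setdiff(names(grades), seg$segment)
  if (length(unknown))
    stop("unknown segment(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(seg$segment, names(grades))
  if (length(missing))
    stop("ungraded segment(s): ", paste(missing, collapse = ", "))
  g <- grades[seg$segment]
  if (any(g != round(g)) || any(g < 0) || any(g > seg$max_grade))
    stop("grades must be integers within each segment's 0..max_grade scale")
  sum(seg$weight * g) + rubric$offset
}

#' Dichotomise PAD severity from the DSA runoff score
#'
#' Mild PAD iff the score is at most 7; severe otherwise.
#'
#' @param dsa_score Numeric score(s) in `[0, 19]`.
#' @return Character vector, `"mild"` or `"severe"`.
#' @examples
#' dichotomize(c(0, 7, 8))
#' @export
dichotomize <- function(dsa_score) {
  if (any(dsa_score < 0 | dsa_score > 19))
    stop("runoff scores must lie in [0, 19]")
  ifelse(dsa_score <= 7, "mild", "severe")
}

#' Inter-reader agreement: ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation with its F-based 95% confidence interval (McGraw & Wong
#' conventions) and the F test against ICC = 0.
#'
#' @param ratings Numeric matrix, subjects in rows and readers in
#'   columns (at least 3 subjects and 2 readers).
#' @param conf Confidence level (default 0.95).
#' @return List with `icc`, `ci` (length 2), `p`, and the mean squares.
#' @export
iccAgreement <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  stopifnot(nrow(ratings) >= 3, ncol(ratings) >= 2,
            all(is.finite(ratings)))
  n <- nrow(ratings)
  k <- ncol(ratings)
  rowMu <- rowMeans(ratings)
  colMu <- colMeans(ratings)
  mu <- mean(ratings)
  MSR <- k * sum((rowMu - mu)^2) / (n - 1)
  MSC <- n * sum((colMu - mu)^2) / (k - 1)
  SSE <- sum((ratings - outer(rowMu, rep(1, k)) -
                outer(rep(1, n), colMu) + mu)^2)
  MSE <- SSE / ((n - 1) * (k - 1))

  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (MSR <= MSE || denom <= 0) {
    warning("no between-subject variance; ICC reported as 0")
    return(list(icc = 0, ci = c(NA_real_, NA_real_), p = NA_real_,
                MSR = MSR, MSC = MSC, MSE = MSE))
  }
  icc <- (MSR - MSE) / denom

  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  p <- pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, ci = c(lower, upper), p = p,
       MSR = MSR, MSC = MSC, MSE = MSE)
}
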