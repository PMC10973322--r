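## Feature-bank front end.

#' Feature names per family
#'
#' @param families Character vector among `"histogram"`, `"glcm"`,
#'   `"gldm"`, `"glrlm"`, `"glszm"`, `"ngtdm"`, `"shape"`; the default is
#'   all seven, giving 95 intensity/texture names followed by 16 shape
#'   names, in the stable extraction order.
#' @return Character vector of feature names.
#' @export
featureNames <- function(families = c("histogram", "glcm", "gldm",
                                      "glrlm", "glszm", "ngtdm", "shape")) {
  families <- match.arg(families, several.ok = TRUE)
  unlist(list(histogram = .histogramNames, glcm = .glcmNames,
              gldm = .gldmNames, glrlm = .glrlmNames,
              glszm = .glszmNames, ngtdm = .ngtdmNames,
              shape = .shapeNames)[families], use.names = FALSE)
}

#' Extract selected feature families from a masked volume
#'
#' @param volume A [CTVolume-class].
#' @param mask A [MuscleMask-class] aligned to it.
#' @param disc A [DiscretizationParams-class].
#' @param families Families to compute (see [featureNames()]).
#' @param features Optional character vector of individual feature names;
#'   only the families needed for them are computed and the result is
#'   restricted to (and ordered as) this vector.
#' @return Named numeric feature vector.
#' @export
extractFeatures <- function(volume, mask, disc = discretizationParams(),
                            families = c("histogram", "glcm", "gldm",
                                         "glrlm", "glszm", "ngtdm",
                                         "shape"),
                            features = NULL) {
  if (!is.null(features)) {
    known <- featureNames()
    bad <- setdiff(features, known)
    if (length(bad))
      stop("unknown feature(s): ", paste(bad, collapse = ", "))
    families <- unique(sub("_.*$", "", features))
  } else {
    families <- match.arg(families, several.ok = TRUE)
  }
  textureFams <- intersect(families, c("glcm", "gldm", "glrlm", "glszm",
                                       "ngtdm"))
  la <- if (length(textureFams)) .levelArray(volume, mask, disc) else NULL
  vals <- list()
  if ("histogram" %in% families)
    vals$histogram <- histogramFeatures(huData(volume)[maskData(mask)],
                                        binWidth = disc@binWidth)
  if ("glcm" %in% families) vals$glcm <- .glcmFromLA(la, disc)
  if ("gldm" %in% families) vals$gldm <- .gldmFromLA(la, disc)
  if ("glrlm" %in% families) vals$glrlm <- .glrlmFromLA(la, disc)
  if ("glszm" %in% families) vals$glszm <- .glszmFromLA(la, disc)
  if ("ngtdm" %in% families) vals$ngtdm <- .ngtdmFromLA(la, disc)
  if ("shape" %in% families) vals$shape <- shapeFeatures(mask)
  out <- unlist(vals, use.names = FALSE)
  names(out) <- unlist(lapply(vals, names), use.names = FALSE)
  if (!is.null(features)) out <- out[features]
  out
}

#' Extract the full feature vector
#'
#' The complete bank: 20 histogram + 24 GLCM + 14 GLDM + 16 GLRLM +
#' 16 GLSZM + 5 NGTDM = 95 intensity/texture features, plus 16 shape
#' features -- 111 named values in a stable order.
#'
#' @inheritParams extractFeatures
#' @return Named numeric vector of 111 features.
#' @export
extractAll <- function(volume, mask, disc = discretizationParams()) {
  extractFeatures(volume, mask, disc)
}
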