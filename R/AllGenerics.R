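## Accessors and show methods.

#' @rdname rasterImage
#' @param object,x a package object.
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))

#' @rdname rasterImage
#' @export
setMethod("imagePixels", "RasterImage", function(x) x@pixels)

#' @rdname rasterImage
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname rasterImage
#' @export
setMethod("imageId", "RasterImage", function(x) x@id)

#' @rdname labelMap
#' @param x a [LabelMap-class].
#' @export
setGeneric("labelCodes", function(x) standardGeneric("labelCodes"))

#' @rdname labelMap
#' @export
setMethod("labelCodes", "LabelMap", function(x) x@labels)

#' @rdname labelMap
#' @export
setGeneric("labelLegend", function(x) standardGeneric("labelLegend"))

#' @rdname labelMap
#' @export
setMethod("labelLegend", "LabelMap", function(x) x@legend)

#' Per-pixel class names of a LabelMap
#'
#' @param x a [LabelMap-class].
#' @return character matrix of class names; `NA` where unclassified.
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' @rdname labelNames
#' @export
setMethod("labelNames", "LabelMap", function(x) {
  out <- matrix(c(NA_character_, x@legend)[x@labels + 1L], nrow(x@labels))
  out
})

#' @rdname composition
#' @param x a [Composition-class].
#' @export
setGeneric("compositionPct", function(x) standardGeneric("compositionPct"))

#' @rdname composition
#' @export
setMethod("compositionPct", "Composition", function(x)
  c(rbc = x@pctRbc, wbc = x@pctWbc, fibrin = x@pctFibrin))

#' @rdname composition
#' @export
setGeneric("pixelCounts", function(x) standardGeneric("pixelCounts"))

#' @rdname composition
#' @export
setMethod("pixelCounts", "Composition", function(x)
  c(tissue = x@nTissuePx, background = x@nBackgroundPx,
    artefact = x@nArtefactPx))

#' Label set of a pixel classifier
#'
#' @param x a [PixelModel-class] or [MainModel-class].
#' @export
setGeneric("modelLabels", function(x) standardGeneric("modelLabels"))

#' @rdname modelLabels
#' @export
setMethod("modelLabels", "PixelModel", function(x) x@labelSet)

#' @rdname modelLabels
#' @export
setMethod("modelLabels", "MainModel", function(x)
  list(exclusion = x@exclusion@labelSet,
       classification = x@classification@labelSet))

setMethod("show", "RasterImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RasterImage '%s': %d x %d px, 3 channels (8-bit)\n",
              object@id, d[1], d[2]))
  if (!is.na(object@pixelSize))
    cat(sprintf("  pixel size: %.4g um/px\n", object@pixelSize))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelMap for '%s': %d x %d px\n", object@imageId, d[1], d[2]))
  tab <- tabulate(object@labels + 1L, nbins = length(object@legend) + 1L)
  nm <- c("unclassified", object@legend)
  keep <- tab > 0
  cat("  ", paste(sprintf("%s: %d", nm[keep], tab[keep]), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "PixelModel", function(object) {
  cat(sprintf("PixelModel over {%s}\n", paste(object@labelSet,
                                              collapse = ", ")))
  cat(sprintf("  RBF SVM: C = %g, gamma = %g; window radius %d; %d features\n",
              object@cost, object@gamma, object@featureConfig@windowRadius,
              length(object@scalerMean)))
  nsv <- sum(vapply(object@pairs, function(p) nrow(p$sv), 0L))
  cat(sprintf("  %d one-vs-one pairs, %d support vectors total\n",
              length(object@pairs), nsv))
})

setMethod("show", "MainModel", function(object) {
  cat("MainModel: exclusion (background/tissue/artefact) composed with\n")
  cat("  classification (rbc/wbc/fibrin) on tissue pixels only\n")
})

setMethod("show", "Composition", function(object) {
  cat(sprintf("Composition '%s': RBC %.1f%%, WBC %.1f%%, fibrin %.1f%%\n",
              object@imageId, object@pctRbc, object@pctWbc, object@pctFibrin))
  cat(sprintf("  tissue %d px, background %d px, artefact %d px; category %s\n",
              as.integer(object@nTissuePx), as.integer(object@nBackgroundPx),
              as.integer(object@nArtefactPx), categorizeClot(object)))
})

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf(
    "Bland-Altman: bias %.3f +/- %.3f (SD), limits of agreement %.3f to %.3f (n = %d)\n",
    object@bias, object@sd, object@loaLow, object@loaHigh, object@n))
})

setMethod("show", "RankCorrelationResult", function(object) {
  cat(sprintf("Spearman rho = %.3f, p = %.3g, n = %d\n",
              object@rho, object@p, object@n))
})

setMethod("show", "ChiSquareResult", function(object) {
  cat(sprintf("Pearson chi-squared: X2(%d) = %.3f, p = %.3g\n",
              object@df, object@statistic, object@p))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport over %d clots\n", object@n))
  cat("  pooled between-method "); show(object@pooledSpearman)
  cat("  pooled "); show(object@pooledBlandAltman)
  for (m in names(object@rbcHuSpearman)) {
    cat(sprintf("  %%RBC vs mean HU [%s]: ", m))
    show(object@rbcHuSpearman[[m]])
  }
  for (m in names(object@hasChi2)) {
    res <- object@hasChi2[[m]]
    cat(sprintf("  HAS association [%s]: ", m))
    if (is.null(res)) cat("undefined (zero margin)\n") else show(res)
  }
})
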