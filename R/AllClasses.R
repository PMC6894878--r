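## Central S4 data model: raster images, annotation regions, label maps,
## feature configuration, pixel classifiers and quantification results.

# Canonical class names used across the pipeline.
EXCLUSION_LABELS <- c("background", "tissue", "artefact")
TISSUE_LABELS <- c("rbc", "wbc", "fibrin")
ALL_LABELS <- c("background", "artefact", "rbc", "wbc", "fibrin")
CATEGORY_LEVELS <- c("RBC_RICH", "MIXED", "FIBRIN_RICH")
MODEL_FORMAT_VERSION <- "1"

#' RasterImage: an 8-bit RGB pixel grid
#'
#' The unit of analysis: a tile or down-sampled whole-slide export stored as
#' an `H x W x 3` integer array of intensities in `[0, 255]`.
#'
#' @slot pixels integer array, `H x W x 3` (rows, columns, RGB channels).
#' @slot pixelSize numeric(1), micrometers per pixel (`NA` if unknown).
#' @slot id character(1), slide/tile identifier, unique within a batch.
#' @exportClass RasterImage
setClass("RasterImage",
  representation(pixels = "array", pixelSize = "numeric", id = "character"))

setValidity("RasterImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (dim(p)[1] < 1L || dim(p)[2] < 1L)
    return("image must have H >= 1 and W >= 1")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("intensities must lie in [0, 255]")
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    return("id must be a non-empty string")
  if (length(object@pixelSize) != 1L)
    return("pixelSize must be a single value (possibly NA)")
  TRUE
})

#' Construct a RasterImage
#'
#' @param pixels numeric/integer `H x W x 3` array (values in 0..255), or an
#'   `H x W` matrix which is replicated across the three channels.
#' @param id slide/tile identifier.
#' @param pixelSize micrometers per pixel, `NA` if unknown.
#' @return A [RasterImage-class] object.
#' @examples
#' img <- rasterImage(array(128L, c(4, 4, 3)), id = "t1")
#' dim(imagePixels(img))
#' @export
rasterImage <- function(pixels, id = "image", pixelSize = NA_real_) {
  if (is.matrix(pixels))
    pixels <- array(pixels, c(dim(pixels), 3L))
  storage.mode(pixels) <- "integer"
  new("RasterImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
      id = as.character(id))
}

#' LabelMap: per-pixel class identifiers
#'
#' @slot labels integer matrix `H x W`; `0` is the reserved "unclassified"
#'   value, positive codes index into `legend`.
#' @slot legend character vector; `legend[k]` is the class name of code `k`.
#' @slot imageId identifier of the image the map describes.
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "matrix", legend = "character",
                 imageId = "character"))

setValidity("LabelMap", function(object) {
  l <- object@labels
  if (!is.integer(l)) return("labels must be an integer matrix")
  u <- unique(as.vector(l))
  if (any(u < 0L) || any(u > length(object@legend)))
    return("every label code must be 0 (unclassified) or index the legend")
  if (anyDuplicated(object@legend)) return("legend names must be unique")
  TRUE
})

#' Construct a LabelMap
#'
#' @param labels integer matrix of class codes (0 = unclassified).
#' @param legend character vector mapping code `k` to a class name.
#' @param imageId identifier of the annotated image.
#' @return A [LabelMap-class] object.
#' @export
labelMap <- function(labels, legend, imageId = "image") {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, legend = as.character(legend),
      imageId = as.character(imageId))
}

#' AnnotationRegion: a labeled polygon, rectangle or ellipse
#'
#' Coordinates are `(row, col)`, 0-based, origin at the top-left pixel
#' center. A polygon is an `n x 2` vertex matrix (n >= 3); a rectangle is a
#' `2 x 2` matrix of two opposite corners; an ellipse is a `2 x 2` matrix of
#' center `(row, col)` and radii `(radius_row, radius_col)`.
#'
#' @slot label class name the region annotates.
#' @slot shape one of `"polygon"`, `"rectangle"`, `"ellipse"`.
#' @slot coords numeric coordinate matrix as described above.
#' @slot imageId identifier of the image the region belongs to.
#' @exportClass AnnotationRegion
setClass("AnnotationRegion",
  representation(label = "character", shape = "character",
                 coords = "matrix", imageId = "character"))

setValidity("AnnotationRegion", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a non-empty string")
  if (!object@shape %in% c("polygon", "rectangle", "ellipse"))
    return("shape must be polygon, rectangle or ellipse")
  co <- object@coords
  if (ncol(co) != 2L || anyNA(co)) return("coords must be an n x 2 matrix")
  if (object@shape == "polygon" && nrow(co) < 3L)
    return("a polygon needs at least 3 vertices")
  if (object@shape %in% c("rectangle", "ellipse") && nrow(co) != 2L)
    return("rectangle/ellipse need a 2 x 2 parameter matrix")
  if (object@shape == "ellipse" && any(co[2L, ] <= 0))
    return("ellipse radii must be positive")
  TRUE
})

#' Construct an AnnotationRegion
#'
#' @param label class name (e.g. `"rbc"`, `"fibrin"`, `"background"`).
#' @param shape `"polygon"`, `"rectangle"` or `"ellipse"`.
#' @param coords coordinate matrix, see [AnnotationRegion-class].
#' @param imageId identifier of the annotated image.
#' @return An [AnnotationRegion-class] object.
#' @examples
#' annotationRegion("rbc", "rectangle", rbind(c(0, 0), c(1, 1)), "t1")
#' @export
annotationRegion <- function(label, shape, coords, imageId = "image") {
  coords <- rbind(coords)
  storage.mode(coords) <- "double"
  new("AnnotationRegion", label = as.character(label),
      shape = as.character(shape), coords = coords,
      imageId = as.character(imageId))
}

#' FeatureConfig: sliding-window feature extraction settings
#'
#' Six per-channel window descriptors (minimum, maximum, mean, population
#' variance, edge factor, center value) over a `(2r+1) x (2r+1)` window on
#' each of the three RGB channels: 18 features in total, ordered
#' channel-major (all six R features, then G, then B).
#'
#' @slot windowRadius integer window radius (at least 1).
#' @slot featureNames the six descriptor names, in output order.
#' @slot channels the channel names, in output order.
#' @exportClass FeatureConfig
setClass("FeatureConfig",
  representation(windowRadius = "integer", featureNames = "character",
                 channels = "character"))

setValidity("FeatureConfig", function(object) {
  if (length(object@windowRadius) != 1L || object@windowRadius < 1L)
    return("windowRadius must be a single integer >= 1")
  if (!identical(object@featureNames,
                 c("min", "max", "mean", "variance", "edge_factor", "center")))
    return("featureNames must be the six canonical descriptors")
  if (!identical(object@channels, c("R", "G", "B")))
    return("channels must be R, G, B")
  TRUE
})

#' Construct a FeatureConfig
#'
#' @param windowRadius window radius in pixels; the default 4 gives a 9 x 9
#'   window, spanning a red blood cell at a typical 20x-derived working
#'   resolution.
#' @return A [FeatureConfig-class] object.
#' @export
featureConfig <- function(windowRadius = 4L) {
  new("FeatureConfig", windowRadius = as.integer(windowRadius),
      featureNames = c("min", "max", "mean", "variance", "edge_factor",
                       "center"),
      channels = c("R", "G", "B"))
}

#' PixelModel: a trained SVM pixel classifier
#'
#' Bundles the feature configuration, the training-data standardization, and
#' the one-vs-one RBF-kernel SVM state needed for deterministic prediction.
#'
#' @slot labelSet ordered class names (ties in voting break by this order).
#' @slot featureConfig the [FeatureConfig-class] used at training time.
#' @slot scalerMean,scalerSd per-feature standardization parameters
#'   (zero-variance features get SD 1 and are flagged in `zeroVariance`).
#' @slot zeroVariance logical flags for features constant in training data.
#' @slot pairs list of one-vs-one binary classifiers, each a list with
#'   elements `classes` (integer pair, indexes into `labelSet`), `sv`
#'   (support-vector matrix), `coef`, `rho`.
#' @slot gamma,cost RBF kernel width and box constraint.
#' @slot trainingMeta list: images used, pixels per class, seed, version.
#' @exportClass PixelModel
setClass("PixelModel",
  representation(labelSet = "character", featureConfig = "FeatureConfig",
                 scalerMean = "numeric", scalerSd = "numeric",
                 zeroVariance = "logical", pairs = "list",
                 gamma = "numeric", cost = "numeric",
                 trainingMeta = "list"))

setValidity("PixelModel", function(object) {
  if (length(object@labelSet) < 2L) return("labelSet needs >= 2 classes")
  if (anyDuplicated(object@labelSet)) return("labelSet must be unique")
  if (any(object@scalerSd <= 0)) return("scaler SDs must be positive")
  nf <- length(object@scalerMean)
  if (length(object@scalerSd) != nf || length(object@zeroVariance) != nf)
    return("scaler components must have equal length")
  k <- length(object@labelSet)
  if (length(object@pairs) != k * (k - 1L) / 2L)
    return("need one binary classifier per unordered class pair")
  TRUE
})

#' MainModel: exclusion composed with classification
#'
#' The combined model: the exclusion stage labels every pixel background /
#' tissue / artefact; the classification stage assigns RBC / WBC / fibrin
#' only on pixels the exclusion stage marked as tissue.
#'
#' @slot exclusion [PixelModel-class] over background / tissue / artefact.
#' @slot classification [PixelModel-class] over rbc / wbc / fibrin.
#' @exportClass MainModel
setClass("MainModel",
  representation(exclusion = "PixelModel", classification = "PixelModel"))

setValidity("MainModel", function(object) {
  if (!setequal(object@exclusion@labelSet, EXCLUSION_LABELS))
    return("exclusion model must have labels background, tissue, artefact")
  if (!setequal(object@classification@labelSet, TISSUE_LABELS))
    return("classification model must have labels rbc, wbc, fibrin")
  TRUE
})

#' Composition: per-slide clot component percentages
#'
#' Percentages of classified tissue pixels (background and artefact pixels
#' are excluded from the denominator); the three percentages sum to 100.
#'
#' @slot pctRbc,pctWbc,pctFibrin percentages of classified tissue pixels.
#' @slot nTissuePx,nBackgroundPx,nArtefactPx pixel counts.
#' @slot imageId slide identifier.
#' @exportClass Composition
setClass("Composition",
  representation(pctRbc = "numeric", pctWbc = "numeric",
                 pctFibrin = "numeric", nTissuePx = "numeric",
                 nBackgroundPx = "numeric", nArtefactPx = "numeric",
                 imageId = "character"))

setValidity("Composition", function(object) {
  p <- c(object@pctRbc, object@pctWbc, object@pctFibrin)
  if (any(p < 0) || any(p > 100)) return("percentages must lie in [0, 100]")
  n <- c(object@nTissuePx, object@nBackgroundPx, object@nArtefactPx)
  if (any(n < 0)) return("pixel counts must be non-negative")
  if (object@nTissuePx > 0 && abs(sum(p) - 100) > 1e-9)
    return("percentages must sum to 100")
  TRUE
})

#' Construct a Composition
#'
#' @param pctRbc,pctWbc,pctFibrin percentages of classified tissue pixels.
#' @param nTissuePx,nBackgroundPx,nArtefactPx pixel counts.
#' @param imageId slide identifier.
#' @return A [Composition-class] object.
#' @export
composition <- function(pctRbc, pctWbc, pctFibrin, nTissuePx = 0,
                        nBackgroundPx = 0, nArtefactPx = 0,
                        imageId = "image") {
  new("Composition", pctRbc = as.numeric(pctRbc), pctWbc = as.numeric(pctWbc),
      pctFibrin = as.numeric(pctFibrin), nTissuePx = as.numeric(nTissuePx),
      nBackgroundPx = as.numeric(nBackgroundPx),
      nArtefactPx = as.numeric(nArtefactPx), imageId = as.character(imageId))
}

#' ColorThreshold: per-channel intensity bounds for one class
#'
#' @slot label class name.
#' @slot low,high inclusive per-channel RGB bounds in `[0, 255]`.
#' @exportClass ColorThreshold
setClass("ColorThreshold",
  representation(label = "character", low = "numeric", high = "numeric"))

setValidity("ColorThreshold", function(object) {
  if (length(object@low) != 3L || length(object@high) != 3L)
    return("low/high must have one bound per RGB channel")
  if (any(object@low > object@high)) return("low must be <= high per channel")
  if (min(object@low) < 0 || max(object@high) > 255)
    return("bounds must lie in [0, 255]")
  TRUE
})

#' BlandAltmanResult: agreement between two paired measurement series
#'
#' @slot bias mean of the paired differences (a - b).
#' @slot sd sample standard deviation (n - 1) of the differences.
#' @slot loaLow,loaHigh 95% limits of agreement, bias -/+ 1.96 sd.
#' @slot n number of pairs.
#' @slot points data.frame of (average, difference) for plotting.
#' @exportClass BlandAltmanResult
setClass("BlandAltmanResult",
  representation(bias = "numeric", sd = "numeric", loaLow = "numeric",
                 loaHigh = "numeric", n = "integer", points = "data.frame"))

setValidity("BlandAltmanResult", function(object) {
  if (abs((object@loaHigh - object@loaLow) - 2 * 1.96 * object@sd) > 1e-9)
    return("limits of agreement must span 2 x 1.96 x sd")
  if (object@loaLow > object@bias + 1e-12 ||
      object@loaHigh < object@bias - 1e-12)
    return("bias must lie between the limits of agreement")
  TRUE
})

#' RankCorrelationResult: Spearman rank correlation
#'
#' @slot rho Spearman correlation coefficient.
#' @slot p two-sided p-value.
#' @slot n number of pairs.
#' @exportClass RankCorrelationResult
setClass("RankCorrelationResult",
  representation(rho = "numeric", p = "numeric", n = "integer"))

setValidity("RankCorrelationResult", function(object) {
  if (object@rho < -1 - 1e-12 || object@rho > 1 + 1e-12)
    return("rho must lie in [-1, 1]")
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  TRUE
})

#' ChiSquareResult: Pearson chi-squared test of association
#'
#' @slot statistic Pearson X-squared statistic.
#' @slot df degrees of freedom, (rows - 1)(cols - 1).
#' @slot p upper-tail p-value.
#' @slot observed,expected contingency tables.
#' @exportClass ChiSquareResult
setClass("ChiSquareResult",
  representation(statistic = "numeric", df = "integer", p = "numeric",
                 observed = "matrix", expected = "matrix"))

setValidity("ChiSquareResult", function(object) {
  if (object@statistic < 0) return("statistic must be non-negative")
  if (any(abs(rowSums(object@expected) - rowSums(object@observed)) > 1e-9) ||
      any(abs(colSums(object@expected) - colSums(object@observed)) > 1e-9))
    return("expected margins must match observed margins")
  TRUE
})

#' AgreementReport: cross-method and clinical statistics for a clot batch
#'
#' @slot pooledSpearman [RankCorrelationResult-class] between the two
#'   methods' pooled per-component percentages.
#' @slot pooledBlandAltman [BlandAltmanResult-class] on the pooled pairs.
#' @slot rbcHuSpearman list of per-method [RankCorrelationResult-class]
#'   objects: percent RBC versus mean Hounsfield Units.
#' @slot hasTables list of per-method 3 x 2 and collapsed 2 x 2 tables.
#' @slot hasChi2 list of per-method [ChiSquareResult-class] objects (or NULL
#'   where a zero margin made the test undefined).
#' @slot n number of clots common to all inputs.
#' @slot clotIds identifiers of those clots.
#' @exportClass AgreementReport
setClass("AgreementReport",
  representation(pooledSpearman = "RankCorrelationResult",
                 pooledBlandAltman = "BlandAltmanResult",
                 rbcHuSpearman = "list", hasTables = "list",
                 hasChi2 = "list", n = "integer", clotIds = "character"))
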