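## Whole-slide quantification: apply the combined model, compute composition
## percentages over classified tissue, categorize clots, and batch mode.

#' Apply a Main model to a slide
#'
#' The exclusion stage labels every pixel background / tissue / artefact;
#' the classification stage then relabels only the tissue pixels as rbc /
#' wbc / fibrin. The result is a five-way label map in which no pixel the
#' exclusion stage rejected carries a tissue-class label.
#'
#' @param main a [MainModel-class].
#' @param image a [RasterImage-class].
#' @param stride prediction stride passed to [predictLabels].
#' @param tileSize tiling limit passed to [predictLabels].
#' @return A [LabelMap-class] with legend background, artefact, rbc, wbc,
#'   fibrin.
#' @export
applyMainModel <- function(main, image, stride = 1L, tileSize = 8192L) {
  stopifnot(is(main, "MainModel"), is(image, "RasterImage"))
  excl <- predictLabels(main@exclusion, image, stride = stride,
                        tileSize = tileSize)
  exLegend <- excl@legend
  tissueCode <- match("tissue", exLegend)
  tissueMask <- excl@labels == tissueCode
  H <- nrow(excl@labels); W <- ncol(excl@labels)
  out <- matrix(0L, H, W)
  out[excl@labels == match("background", exLegend)] <- 1L
  out[excl@labels == match("artefact", exLegend)] <- 2L
  if (any(tissueMask)) {
    cls <- predictLabels(main@classification, image, mask = tissueMask,
                         stride = stride, tileSize = tileSize)
    codeMap <- match(cls@legend, ALL_LABELS)  # rbc/wbc/fibrin -> 3/4/5
    out[tissueMask] <- codeMap[cls@labels[tissueMask]]
  }
  labelMap(out, ALL_LABELS, imageId = image@id)
}

#' Composition percentages from a label map
#'
#' Percentages are taken over classified tissue pixels only (rbc + wbc +
#' fibrin); background and artefact are excluded from the denominator but
#' their counts are reported.
#'
#' @param labels a [LabelMap-class] whose legend uses the canonical class
#'   names.
#' @return A [Composition-class].
#' @export
compositionFromLabels <- function(labels) {
  stopifnot(is(labels, "LabelMap"))
  legend <- labels@legend
  cnt <- tabulate(labels@labels, nbins = length(legend))
  n <- function(cls) { i <- match(cls, legend); if (is.na(i)) 0 else cnt[i] }
  tissue <- n("rbc") + n("wbc") + n("fibrin")
  if (tissue == 0) stop("no tissue detected in '", labels@imageId, "'")
  composition(100 * n("rbc") / tissue, 100 * n("wbc") / tissue,
              100 * n("fibrin") / tissue, nTissuePx = tissue,
              nBackgroundPx = n("background"), nArtefactPx = n("artefact"),
              imageId = labels@imageId)
}

#' Categorize a clot from its composition
#'
#' RBC-rich if the RBC percentage is >= 60, fibrin-rich if the fibrin
#' percentage is >= 60, otherwise mixed (the three-way scheme has no
#' WBC-dominant class, so a composition below 60% in both RBC and fibrin is
#' mixed even if the WBC share is large).
#'
#' @param comp a [Composition-class].
#' @return `"RBC_RICH"`, `"MIXED"` or `"FIBRIN_RICH"`.
#' @examples
#' categorizeClot(composition(70, 5, 25, nTissuePx = 100))
#' @export
categorizeClot <- function(comp) {
  stopifnot(is(comp, "Composition"))
  if (comp@pctRbc >= 60) "RBC_RICH"
  else if (comp@pctFibrin >= 60) "FIBRIN_RICH"
  else "MIXED"
}

#' Batch quantification of a slide set
#'
#' Applies a [MainModel-class] to every image; per-image failures (for
#' example an all-background slide with no detectable tissue) are recorded
#' in the `note` column of that row and do not abort the batch.
#'
#' @param main a [MainModel-class].
#' @param images list of [RasterImage-class].
#' @param stride,tileSize passed to [applyMainModel].
#' @return data.frame with one row per image: `image_id`, `pct_rbc`,
#'   `pct_wbc`, `pct_fibrin`, `n_tissue_px`, `n_background_px`,
#'   `n_artefact_px`, `category`, `note` (`""` for clean rows).
#' @export
batchQuantify <- function(main, images, stride = 1L, tileSize = 8192L) {
  stopifnot(is(main, "MainModel"))
  if (length(images) == 0L) stop("empty image list")
  stopifnot(all(vapply(images, is, TRUE, "RasterImage")))
  rows <- lapply(images, function(img) {
    tryCatch({
      lm <- applyMainModel(main, img, stride = stride, tileSize = tileSize)
      comp <- compositionFromLabels(lm)
      data.frame(image_id = img@id, pct_rbc = comp@pctRbc,
                 pct_wbc = comp@pctWbc, pct_fibrin = comp@pctFibrin,
                 n_tissue_px = comp@nTissuePx,
                 n_background_px = comp@nBackgroundPx,
                 n_artefact_px = comp@nArtefactPx,
                 category = categorizeClot(comp), note = "")
    }, error = function(e) {
      data.frame(image_id = img@id, pct_rbc = NA_real_, pct_wbc = NA_real_,
                 pct_fibrin = NA_real_, n_tissue_px = NA_real_,
                 n_background_px = NA_real_, n_artefact_px = NA_real_,
                 category = NA_character_, note = conditionMessage(e))
    })
  })
  do.call(rbind, rows)
}
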