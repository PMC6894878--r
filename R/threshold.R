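## Reference-standard comparator: representative-region color thresholding
## with manual artefact cropping, emulating the image-editing workflow it
## replaces. Deliberately keeps that method's character: a single
## representative region per class defines per-channel intensity bounds, so
## its accuracy depends entirely on how representative the region is.

#' Derive a color threshold from a representative region
#'
#' Per-channel bounds are the minimum and maximum intensities of the
#' region's pixels, widened by `tolerance` and clipped to `[0, 255]`.
#' Exactly one representative region per class is the intended use.
#'
#' @param image a [RasterImage-class].
#' @param region an [AnnotationRegion-class]; its label names the class.
#' @param tolerance intensity units added on both sides (default 0).
#' @return A [ColorThreshold-class].
#' @export
thresholdFromRegion <- function(image, region, tolerance = 0) {
  stopifnot(is(image, "RasterImage"), is(region, "AnnotationRegion"),
            tolerance >= 0)
  mask <- rasterizeRegion(region, dim(image@pixels)[1:2])
  low <- high <- numeric(3)
  for (ch in 1:3) {
    v <- image@pixels[, , ch][mask]
    low[ch] <- max(0, min(v) - tolerance)
    high[ch] <- min(255, max(v) + tolerance)
  }
  new("ColorThreshold", label = region@label, low = low, high = high)
}

#' Quantify a slide by color thresholding
#'
#' Artefact crop regions are removed first; a remaining pixel matches a
#' class iff all three channels fall within that class's bounds. Pixels
#' matching several classes are assigned to the class whose color centroid
#' (midpoint of its bounds) is nearest in RGB distance (ties broken by the
#' order of `thresholds`); pixels matching none are "unmatched".
#'
#' @param image a [RasterImage-class].
#' @param thresholds list of [ColorThreshold-class], one per tissue class
#'   (rbc, wbc, fibrin); order fixes the multi-match tie-break.
#' @param cropRegions list of [AnnotationRegion-class] to crop out (may be
#'   empty).
#' @param denominator `"whole_image"` (the manual method's convention: all
#'   un-cropped pixels) or `"tissue"` (matched tissue pixels only, for
#'   apples-to-apples comparison with the ML pipeline).
#' @return A list with `pct` (named rbc/wbc/fibrin percentages under the
#'   chosen denominator), `pct_unmatched`, `counts` (matched counts per
#'   class plus `unmatched` and `cropped`), `denominator`, `image_id`.
#' @export
thresholdQuantify <- function(image, thresholds, cropRegions = list(),
                              denominator = c("whole_image", "tissue")) {
  stopifnot(is(image, "RasterImage"),
            all(vapply(thresholds, is, TRUE, "ColorThreshold")))
  denominator <- match.arg(denominator)
  labs <- vapply(thresholds, function(t) t@label, "")
  if (!all(TISSUE_LABELS %in% labs))
    stop("thresholds must cover the classes rbc, wbc, fibrin")
  if (anyDuplicated(labs)) stop("one threshold per class, got duplicates")
  for (i in seq_along(thresholds)) for (j in seq_along(thresholds)) {
    if (i < j && identical(thresholds[[i]]@low, thresholds[[j]]@low) &&
        identical(thresholds[[i]]@high, thresholds[[j]]@high))
      stop("identical thresholds for '", labs[i], "' and '", labs[j], "'")
  }
  H <- dim(image@pixels)[1]; W <- dim(image@pixels)[2]
  cropped <- matrix(FALSE, H, W)
  for (r in cropRegions) cropped <- cropped | rasterizeRegion(r, c(H, W))

  k <- length(thresholds)
  dist2 <- array(Inf, c(H, W, k))
  for (i in seq_len(k)) {
    t <- thresholds[[i]]
    match_i <- matrix(TRUE, H, W)
    d2 <- matrix(0, H, W)
    centroid <- (t@low + t@high) / 2
    for (ch in 1:3) {
      v <- image@pixels[, , ch]
      match_i <- match_i & v >= t@low[ch] & v <= t@high[ch]
      d2 <- d2 + (v - centroid[ch])^2
    }
    d2[!match_i] <- Inf
    dist2[, , i] <- d2
  }
  flat <- matrix(dist2, H * W, k)
  best <- max.col(-flat, ties.method = "first")
  assigned <- ifelse(is.finite(flat[cbind(seq_len(H * W), best)]), best, 0L)
  assigned[as.vector(cropped)] <- -1L

  counts <- vapply(seq_len(k), function(i) sum(assigned == i), 0)
  names(counts) <- labs
  nUnmatched <- sum(assigned == 0L)
  nCropped <- sum(assigned == -1L)
  tissueTotal <- sum(counts[TISSUE_LABELS])
  denomN <- if (denominator == "tissue") tissueTotal else H * W - nCropped
  if (denomN == 0) stop("no tissue detected by thresholds in '",
                        image@id, "'")
  pct <- 100 * counts[TISSUE_LABELS] / denomN
  list(pct = pct, pct_unmatched = 100 * nUnmatched / denomN,
       counts = c(counts, unmatched = nUnmatched, cropped = nCropped),
       denominator = denominator, image_id = image@id)
}

#' Threshold-quantify a batch of slides
#'
#' Convenience wrapper producing a table shaped like [batchQuantify]'s
#' output, using each slide's own representative regions.
#'
#' @param images list of [RasterImage-class].
#' @param regionSets list (parallel to `images`) of lists of
#'   [AnnotationRegion-class]; for each image, the first region of each
#'   tissue class is used as its representative region and artefact regions
#'   are used as crops.
#' @param tolerance passed to [thresholdFromRegion].
#' @param denominator passed to [thresholdQuantify].
#' @return data.frame with columns `image_id`, `pct_rbc`, `pct_wbc`,
#'   `pct_fibrin`, `pct_unmatched`, `category`, `note`.
#' @export
thresholdQuantifyBatch <- function(images, regionSets, tolerance = 0,
                                   denominator = "tissue") {
  stopifnot(length(images) == length(regionSets))
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]; regs <- regionSets[[i]]
    tryCatch({
      labs <- vapply(regs, function(r) r@label, "")
      thr <- lapply(TISSUE_LABELS, function(cls) {
        sel <- which(labs == cls)
        if (!length(sel)) stop("no representative region for '", cls, "'")
        thresholdFromRegion(img, regs[[sel[1]]], tolerance)
      })
      crops <- regs[labs == "artefact"]
      q <- thresholdQuantify(img, thr, crops, denominator)
      category <- if (denominator == "tissue") {
        categorizeClot(composition(q$pct["rbc"], q$pct["wbc"],
                                   q$pct["fibrin"],
                                   nTissuePx = sum(q$counts[TISSUE_LABELS]),
                                   imageId = img@id))
      } else NA_character_
      data.frame(image_id = img@id, pct_rbc = q$pct[["rbc"]],
                 pct_wbc = q$pct[["wbc"]], pct_fibrin = q$pct[["fibrin"]],
                 pct_unmatched = q$pct_unmatched, category = category,
                 note = "")
    }, error = function(e) {
      data.frame(image_id = img@id, pct_rbc = NA_real_, pct_wbc = NA_real_,
                 pct_fibrin = NA_real_, pct_unmatched = NA_real_,
                 category = NA_character_, note = conditionMessage(e))
    })
  })
  do.call(rbind, rows)
}
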