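## Annotation regions: rasterization to pixel masks and the plain-text
## annotation file format (one tab-separated record per region).
##
## Coordinate convention: (row, col), 0-based, origin at the top-left pixel
## center; a pixel belongs to a polygon iff its center satisfies the
## even-odd rule, and to an ellipse iff its center satisfies the ellipse
## inequality.

#' Rasterize an annotation region to a pixel mask
#'
#' @param region an [AnnotationRegion-class].
#' @param extent integer `c(H, W)` of the target image.
#' @return Logical `H x W` matrix, `TRUE` inside the region (clipped to the
#'   extent).
#' @examples
#' r <- annotationRegion("rbc", "rectangle", rbind(c(0, 0), c(1, 1)))
#' sum(rasterizeRegion(r, c(4, 4)))  # 4 pixels
#' @export
rasterizeRegion <- function(region, extent) {
  stopifnot(is(region, "AnnotationRegion"), length(extent) == 2L)
  H <- as.integer(extent[1]); W <- as.integer(extent[2])
  mask <- matrix(FALSE, H, W)
  co <- region@coords
  if (region@shape == "rectangle") {
    r0 <- max(0L, ceiling(min(co[, 1]))); r1 <- min(H - 1L, floor(max(co[, 1])))
    c0 <- max(0L, ceiling(min(co[, 2]))); c1 <- min(W - 1L, floor(max(co[, 2])))
    if (r0 <= r1 && c0 <= c1)
      mask[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] <- TRUE
  } else if (region@shape == "ellipse") {
    ctr <- co[1, ]; rad <- co[2, ]
    r0 <- max(0L, ceiling(ctr[1] - rad[1])); r1 <- min(H - 1L, floor(ctr[1] + rad[1]))
    c0 <- max(0L, ceiling(ctr[2] - rad[2])); c1 <- min(W - 1L, floor(ctr[2] + rad[2]))
    if (r0 <= r1 && c0 <= c1) {
      rr <- r0:r1; cc <- c0:c1
      d <- outer(((rr - ctr[1]) / rad[1])^2, ((cc - ctr[2]) / rad[2])^2, `+`)
      mask[rr + 1L, cc + 1L] <- d <= 1
    }
  } else {  # polygon, even-odd rule on pixel centers
    r0 <- max(0L, ceiling(min(co[, 1]))); r1 <- min(H - 1L, floor(max(co[, 1])))
    c0 <- max(0L, ceiling(min(co[, 2]))); c1 <- min(W - 1L, floor(max(co[, 2])))
    if (r0 <= r1 && c0 <= c1) {
      rr <- rep(r0:r1, times = c1 - c0 + 1L)
      cc <- rep(c0:c1, each = r1 - r0 + 1L)
      inside <- rep(FALSE, length(rr))
      n <- nrow(co)
      j <- n
      for (i in seq_len(n)) {
        ri <- co[i, 1]; ci <- co[i, 2]; rj <- co[j, 1]; cj <- co[j, 2]
        crosses <- (ri > rr) != (rj > rr)
        if (any(crosses)) {
          xint <- (cj - ci) * (rr[crosses] - ri) / (rj - ri) + ci
          inside[crosses] <- xor(inside[crosses], cc[crosses] < xint)
        }
        j <- i
      }
      mask[cbind(rr + 1L, cc + 1L)] <- inside
    }
  }
  if (!any(mask)) stop("empty region: '", region@label,
                       "' rasterizes to no pixels inside the extent")
  mask
}

.coordsToString <- function(co) {
  paste(apply(co, 1L, function(v) paste0(format(v[1], scientific = FALSE,
                                                trim = TRUE), ",",
                                         format(v[2], scientific = FALSE,
                                                trim = TRUE))),
        collapse = ";")
}

.coordsFromString <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  co <- do.call(rbind, lapply(parts, as.numeric))
  if (anyNA(co)) stop("malformed coordinate list: ", s)
  co
}

#' Read and write annotation files
#'
#' The annotation format is a tab-separated text file with a header line and
#' one record per region: `image_id`, `label`, `shape`, `coords`, where
#' `coords` is a `;`-separated list of `row,col` pairs (0-based pixel
#' coordinates; for an ellipse, the two pairs are center and radii).
#'
#' @param path annotation file path.
#' @return `readAnnotations`: a list of [AnnotationRegion-class] objects.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("image_id", "label", "shape", "coords")
  if (!all(need %in% names(tab)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    annotationRegion(tab$label[i], tab$shape[i],
                     .coordsFromString(tab$coords[i]), tab$image_id[i]))
}

#' @rdname readAnnotations
#' @param regions list of [AnnotationRegion-class] objects.
#' @return `writeAnnotations`: `path`, invisibly.
#' @export
writeAnnotations <- function(regions, path) {
  stopifnot(all(vapply(regions, is, TRUE, "AnnotationRegion")))
  tab <- data.frame(
    image_id = vapply(regions, function(r) r@imageId, ""),
    label = vapply(regions, function(r) r@label, ""),
    shape = vapply(regions, function(r) r@shape, ""),
    coords = vapply(regions, function(r) .coordsToString(r@coords), ""))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relabel annotation regions
#'
#' Convenience for preparing exclusion-model training data, where regions
#' annotated with tissue classes (rbc/wbc/fibrin) all count as `tissue`.
#'
#' @param regions list of [AnnotationRegion-class] objects.
#' @param map named character vector, `old label = new label`; labels not in
#'   `map` are kept.
#' @return List of regions with labels substituted.
#' @examples
#' r <- annotationRegion("rbc", "rectangle", rbind(c(0, 0), c(1, 1)))
#' relabelRegions(list(r), c(rbc = "tissue"))[[1]]
#' @export
relabelRegions <- function(regions,
                           map = c(rbc = "tissue", wbc = "tissue",
                                   fibrin = "tissue")) {
  lapply(regions, function(r) {
    if (r@label %in% names(map)) r@label <- unname(map[r@label])
    r
  })
}
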