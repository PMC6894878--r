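## Synthetic H&E-like clot slides with pixel-level ground truth.
##
## A slide is a connected tissue blob on a near-white background. Inside the
## tissue, WBC discs (radius 5-7 px, darker nuclear rim) and RBC discs
## (radius 3-5 px) are painted over a fibrin matrix until the requested
## area fractions are reached; the remaining tissue is fibrin, rendered with
## a smooth strand-like brightness modulation. Optional dark fold artefacts
## overlay the slide as curved bands and replace the underlying ground-truth
## labels with "artefact". Per-pixel color is the class mean plus Gaussian
## noise, followed by a mild spatial blur (sigma 0.5 px).

.defaultClassColors <- function() {
  rbind(background = c(247, 246, 245), artefact = c(45, 40, 45),
        rbc = c(190, 55, 65), wbc = c(85, 60, 140),
        fibrin = c(230, 165, 180))
}

#' SynthParams: parameters of the synthetic clot-slide generator
#'
#' @slot height,width image size in pixels.
#' @slot targetFractions named fractions (rbc, wbc, fibrin) of tissue area;
#'   must be non-negative and sum to 1.
#' @slot backgroundFraction requested fraction of the image that is
#'   background (approximate; the blob outline is randomized).
#' @slot nArtefactFolds number of dark fold bands.
#' @slot classColors 5 x 3 matrix of mean RGB per class (rows background,
#'   artefact, rbc, wbc, fibrin).
#' @slot noiseSd Gaussian intensity noise SD.
#' @slot seed integer RNG seed; identical seeds give bit-identical output.
#' @exportClass SynthParams
setClass("SynthParams",
  representation(height = "integer", width = "integer",
                 targetFractions = "numeric", backgroundFraction = "numeric",
                 nArtefactFolds = "integer", classColors = "matrix",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SynthParams", function(object) {
  tf <- object@targetFractions
  if (!identical(names(tf), c("rbc", "wbc", "fibrin")))
    return("targetFractions must be named rbc, wbc, fibrin")
  if (any(tf < 0) || abs(sum(tf) - 1) > 1e-9)
    return("targetFractions must be non-negative and sum to 1")
  if (object@backgroundFraction < 0 || object@backgroundFraction >= 1)
    return("backgroundFraction must lie in [0, 1)")
  nt <- object@height * object@width * (1 - object@backgroundFraction)
  if (nt < 1000) return("too little tissue: height*width*(1-bg) must be >= 1000")
  if (!identical(rownames(object@classColors), ALL_LABELS) ||
      ncol(object@classColors) != 3L)
    return("classColors must be a 5 x 3 matrix with the canonical class rows")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  if (object@nArtefactFolds < 0) return("nArtefactFolds must be >= 0")
  TRUE
})

#' Construct SynthParams
#'
#' @param height,width image size in pixels.
#' @param targetFractions tissue-area fractions for rbc, wbc, fibrin.
#' @param backgroundFraction requested background fraction of the image.
#' @param nArtefactFolds number of dark fold bands.
#' @param classColors mean RGB per class; defaults emulate H&E (RBC red,
#'   WBC blue-purple, fibrin pink, background near white, artefact dark).
#' @param noiseSd Gaussian intensity noise SD (default 8 intensity units).
#' @param seed integer RNG seed.
#' @return A [SynthParams-class] object.
#' @export
synthParams <- function(height = 192L, width = 192L,
                        targetFractions = c(rbc = 0.6, wbc = 0.1,
                                            fibrin = 0.3),
                        backgroundFraction = 0.3, nArtefactFolds = 0L,
                        classColors = .defaultClassColors(), noiseSd = 8,
                        seed = 1L) {
  tf <- as.numeric(targetFractions)
  names(tf) <- names(targetFractions)
  new("SynthParams", height = as.integer(height), width = as.integer(width),
      targetFractions = tf,
      backgroundFraction = as.numeric(backgroundFraction),
      nArtefactFolds = as.integer(nArtefactFolds),
      classColors = classColors, noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# Paint discs of class `code` onto pixels currently labeled fibrin (code 5)
# until `target` pixels carry `code`. Returns the updated labels, the discs
# placed, and whether the target was reached.
.paintDiscs <- function(labels, code, target, rmin, rmax, tissueIdx, H, W) {
  discs <- list()
  if (target <= 0) return(list(labels = labels, discs = discs, count = 0L,
                               reached = TRUE))
  discArea <- pi * ((rmin + rmax) / 2)^2
  maxAttempts <- ceiling(4 * (target / discArea + 1) *
                           (log(length(tissueIdx)) + 5)) + 500L
  count <- 0L; attempts <- 0L
  while (count < target && attempts < maxAttempts) {
    attempts <- attempts + 1L
    idx <- tissueIdx[sample.int(length(tissueIdx), 1L)]
    r0 <- (idx - 1L) %% H; c0 <- (idx - 1L) %/% H
    rad <- stats::runif(1, rmin, rmax)
    rows <- max(0, ceiling(r0 - rad)):min(H - 1, floor(r0 + rad))
    cols <- max(0, ceiling(c0 - rad)):min(W - 1, floor(c0 + rad))
    inside <- outer((rows - r0)^2, (cols - c0)^2, `+`) <= rad^2
    lin <- outer(rows + 1L, cols * H, `+`)[inside]
    paintable <- lin[labels[lin] == 5L]
    if (length(paintable)) {
      labels[paintable] <- code
      count <- count + length(paintable)
      discs[[length(discs) + 1L]] <- c(r0, c0, rad)
    }
  }
  list(labels = labels, discs = discs, count = count,
       reached = count >= target)
}

.blur05 <- function(m) {
  w <- c(exp(-2), 1, exp(-2)); w <- w / sum(w)
  H <- nrow(m); W <- ncol(m)
  p <- .padSymmetric(m, 1L)
  q <- w[1] * p[1:H, , drop = FALSE] + w[2] * p[2:(H + 1), , drop = FALSE] +
    w[3] * p[3:(H + 2), , drop = FALSE]
  w[1] * q[, 1:W, drop = FALSE] + w[2] * q[, 2:(W + 1), drop = FALSE] +
    w[3] * q[, 3:(W + 2), drop = FALSE]
}

#' Generate a synthetic clot slide with ground truth
#'
#' @param params a [SynthParams-class].
#' @param id identifier for the generated image (default derived from the
#'   seed).
#' @return A list with elements `image` ([RasterImage-class]), `truth`
#'   ([LabelMap-class] over background / artefact / rbc / wbc / fibrin), and
#'   `fractions` (realized rbc/wbc/fibrin fractions over tissue pixels,
#'   summing to 1).
#' @examples
#' s <- generateClotSlide(synthParams(seed = 7))
#' s$fractions
#' @export
generateClotSlide <- function(params, id = NULL) {
  stopifnot(is(params, "SynthParams"))
  if (is.null(id)) id <- sprintf("synth-%d", params@seed)
  H <- params@height; W <- params@width
  .withSeed(params@seed, {
    # star-shaped tissue blob with a wobbled elliptical outline
    ci <- (H - 1) / 2; cj <- (W - 1) / 2
    s <- min(sqrt((1 - params@backgroundFraction) / pi), 0.48)
    a <- H * s; b <- W * s
    amp <- stats::runif(3, 0.02, 0.08)
    ph <- stats::runif(3, 0, 2 * pi)
    freq <- c(2, 3, 5)
    rr <- matrix(0:(H - 1), H, W)
    cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
    rho <- sqrt(((rr - ci) / a)^2 + ((cc - cj) / b)^2)
    th <- atan2(rr - ci, cc - cj)
    bound <- 1 + amp[1] * sin(freq[1] * th + ph[1]) +
      amp[2] * sin(freq[2] * th + ph[2]) + amp[3] * sin(freq[3] * th + ph[3])
    tissue <- rho <= bound
    nT <- sum(tissue)
    if (nT < 1000) stop("degenerate blob: fewer than 1000 tissue pixels")

    labels <- matrix(1L, H, W)        # background
    labels[tissue] <- 5L              # fibrin matrix to start
    tissueIdx <- which(tissue)

    tf <- params@targetFractions
    wres <- .paintDiscs(labels, 4L, round(tf["wbc"] * nT), 5, 7, tissueIdx,
                        H, W)
    if (!wres$reached)
      stop(sprintf("infeasible wbc fraction %.3f: maximum achievable %.3f",
                   tf["wbc"], wres$count / nT))
    labels <- wres$labels
    rres <- .paintDiscs(labels, 3L, round(tf["rbc"] * nT), 3, 5, tissueIdx,
                        H, W)
    if (!rres$reached)
      stop(sprintf("infeasible rbc fraction %.3f: maximum achievable %.3f",
                   tf["rbc"], rres$count / nT))
    labels <- rres$labels

    # rendering: class mean color, WBC rim darkening, fibrin strands
    shade <- matrix(1, H, W)
    for (d in wres$discs) {
      rad <- d[3]
      rows <- max(0, ceiling(d[1] - rad)):min(H - 1, floor(d[1] + rad))
      cols <- max(0, ceiling(d[2] - rad)):min(W - 1, floor(d[2] + rad))
      dist2 <- outer((rows - d[1])^2, (cols - d[2])^2, `+`)
      ring <- dist2 <= rad^2 & dist2 > (rad - 1.8)^2
      lin <- outer(rows + 1L, cols * H, `+`)[ring]
      lin <- lin[labels[lin] == 4L]
      shade[lin] <- 0.6
    }
    dirs <- stats::runif(2, 0, 2 * pi)
    lam <- stats::runif(2, 8, 16)
    strand <- 1 + 0.10 *
      sin(2 * pi * (rr * sin(dirs[1]) + cc * cos(dirs[1])) / lam[1]) *
      sin(2 * pi * (rr * sin(dirs[2]) + cc * cos(dirs[2])) / lam[2])
    fib <- labels == 5L
    shade[fib] <- shade[fib] * strand[fib]

    img <- array(0, c(H, W, 3L))
    for (ch in 1:3) {
      base <- matrix(params@classColors[labels, ch], H, W) * shade
      base <- base + matrix(stats::rnorm(H * W, 0, params@noiseSd), H, W)
      img[, , ch] <- .blur05(base)
    }

    # fold artefacts: quadratic bezier bands, drawn last so that the
    # fold-free rendering of the same seed is bit-identical elsewhere
    if (params@nArtefactFolds > 0) {
      fold <- matrix(FALSE, H, W)
      for (k in seq_len(params@nArtefactFolds)) {
        if (stats::runif(1) < 0.5) {
          p0 <- c(stats::runif(1, 0, H - 1), 0)
          p2 <- c(stats::runif(1, 0, H - 1), W - 1)
        } else {
          p0 <- c(0, stats::runif(1, 0, W - 1))
          p2 <- c(H - 1, stats::runif(1, 0, W - 1))
        }
        p1 <- c(stats::runif(1, 0.2, 0.8) * (H - 1),
                stats::runif(1, 0.2, 0.8) * (W - 1))
        tt <- seq(0, 1, length.out = 4L * (H + W))
        pr <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
        pc <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
        half <- stats::runif(1, 5, 9) / 2
        hw <- ceiling(half)
        for (q in seq_along(tt)) {
          rows <- max(0, round(pr[q]) - hw):min(H - 1, round(pr[q]) + hw)
          cols <- max(0, round(pc[q]) - hw):min(W - 1, round(pc[q]) + hw)
          inside <- outer((rows - pr[q])^2, (cols - pc[q])^2, `+`) <= half^2
          fold[outer(rows + 1L, cols * H, `+`)[inside]] <- TRUE
        }
      }
      labels[fold] <- 2L
      nf <- sum(fold)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[fold] <- 0.25 * plane[fold] + 0.75 * params@classColors[2, ch] +
          stats::rnorm(nf, 0, params@noiseSd / 2)
        img[, , ch] <- plane
      }
    }

    img <- pmin(pmax(round(img), 0), 255)
    counts <- tabulate(labels, nbins = 5L)[3:5]
    fractions <- counts / sum(counts)
    names(fractions) <- TISSUE_LABELS
    list(image = rasterImage(img, id = id),
         truth = labelMap(labels, ALL_LABELS, imageId = id),
         fractions = fractions)
  })
}

# Pure single-class rectangular patches sampled from a ground-truth map.
.sampleClassRegions <- function(truth, code, quota, imageId) {
  lab <- truth@labels
  H <- nrow(lab); W <- ncol(lab)
  ind <- lab == code
  if (!any(ind)) return(NULL)
  selected <- matrix(FALSE, H, W)
  regions <- list(); total <- 0L
  for (hw in c(3L, 2L, 1L, 0L)) {
    if (total >= quota) break
    if (hw > 0L) {
      padded <- matrix(0, H + 2L * hw, W + 2L * hw)
      padded[(hw + 1L):(hw + H), (hw + 1L):(hw + W)] <- ind
      pure <- .boxSum(padded, hw, H, W) == (2L * hw + 1L)^2
    } else pure <- ind
    cand <- which(pure)
    if (!length(cand)) next
    cand <- cand[sample.int(length(cand))]
    for (idx in cand) {
      r0 <- (idx - 1L) %% H; c0 <- (idx - 1L) %/% H   # 0-based center
      rows <- (r0 - hw):(r0 + hw); cols <- (c0 - hw):(c0 + hw)
      patch <- outer(rows + 1L, cols * H, `+`)
      if (any(selected[patch])) next
      selected[patch] <- TRUE
      regions[[length(regions) + 1L]] <- annotationRegion(
        ALL_LABELS[code], "rectangle",
        rbind(c(r0 - hw, c0 - hw), c(r0 + hw, c0 + hw)), imageId)
      total <- total + length(patch)
      if (total >= quota) break
    }
  }
  list(regions = regions, pixels = total)
}

#' Generate an annotated synthetic training/validation set
#'
#' Generates `nImages` slides (seeds `params@seed`, `params@seed + 1`, ...)
#' and, for each, emits pure single-class rectangular annotation regions
#' sampled from the ground truth, covering all five classes where present,
#' with at least `pixelsPerClass` annotated pixels per class per image where
#' achievable.
#'
#' @param params a [SynthParams-class]; slide `k` uses seed
#'   `params@seed + k - 1`.
#' @param nImages number of slides (the workflow expects >= 5 for training).
#' @param pixelsPerClass annotation quota per class per image.
#' @return A list of length `nImages`; each element has `image`, `truth`,
#'   `fractions`, `regions` (list of [AnnotationRegion-class]), and
#'   `warnings` (character, e.g. classes absent from the ground truth).
#' @export
generateAnnotatedSet <- function(params, nImages = 5L,
                                 pixelsPerClass = 2000L) {
  stopifnot(is(params, "SynthParams"), nImages >= 1L)
  out <- vector("list", nImages)
  for (k in seq_len(nImages)) {
    pk <- params
    pk@seed <- params@seed + k - 1L
    slide <- generateClotSlide(pk)
    regions <- list(); warnings <- character(0)
    .withSeed(pk@seed + 7919L, {
      for (code in seq_along(ALL_LABELS)) {
        res <- .sampleClassRegions(slide$truth, code, pixelsPerClass,
                                   imageId = slide$image@id)
        if (is.null(res)) {
          warnings <- c(warnings, sprintf(
            "class '%s' absent from ground truth of %s; omitted",
            ALL_LABELS[code], slide$image@id))
        } else {
          if (res$pixels < pixelsPerClass)
            warnings <- c(warnings, sprintf(
              "class '%s' in %s: only %d pure annotated pixels (quota %d)",
              ALL_LABELS[code], slide$image@id, res$pixels, pixelsPerClass))
          regions <- c(regions, res$regions)
        }
      }
    })
    out[[k]] <- c(slide, list(regions = regions, warnings = warnings))
  }
  out
}
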