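## Pixel classifiers: balanced training-pixel sampling from annotations,
## one-vs-one RBF-kernel SVM training (in-package SMO solver, src/smo.cpp),
## deterministic prediction, model combination, and a single-file container
## format (text header + binary classifier block + integrity checksum).

#' Sample labeled training pixels from annotated images
#'
#' For each class, up to `perClass` pixel locations are drawn uniformly
#' without replacement (seeded) from the union of that class's rasterized
#' regions across all images; the 18 sliding-window features are extracted
#' at each location. Classes with fewer annotated pixels contribute all of
#' them, with a warning record.
#'
#' @param images list of [RasterImage-class]; regions refer to them by id.
#' @param regions list of [AnnotationRegion-class].
#' @param perClass target number of pixels per class (default 5000).
#' @param seed integer seed for the subsampling.
#' @param config a [FeatureConfig-class].
#' @return list with `x` (n x 18 feature matrix), `y` (character class
#'   labels), and `warnings` (character).
#' @export
sampleTrainingPixels <- function(images, regions, perClass = 5000L,
                                 seed = 1L, config = featureConfig()) {
  stopifnot(all(vapply(images, is, TRUE, "RasterImage")),
            all(vapply(regions, is, TRUE, "AnnotationRegion")))
  ids <- vapply(images, imageId, "")
  if (anyDuplicated(ids)) stop("image ids must be unique within a batch")
  labels <- unique(vapply(regions, function(r) r@label, ""))
  # per image, rasterize the union mask of each class
  loc <- list()  # per class: matrix (imageIdx, row0, col0)
  for (lab in labels) loc[[lab]] <- NULL
  for (ii in seq_along(images)) {
    ext <- dim(images[[ii]]@pixels)[1:2]
    for (r in regions) {
      if (r@imageId != ids[ii]) next
      m <- rasterizeRegion(r, ext)
      w <- which(m)
      rows <- (w - 1L) %% ext[1]; cols <- (w - 1L) %/% ext[1]
      loc[[r@label]] <- rbind(loc[[r@label]], cbind(ii, rows, cols))
    }
  }
  warnings <- character(0)
  picked <- list()
  .withSeed(seed, {
    for (lab in labels) {
      m <- unique(loc[[lab]])
      if (is.null(m) || nrow(m) == 0L)
        stop("class '", lab, "' has zero annotated pixels")
      if (nrow(m) <= perClass) {
        if (nrow(m) < perClass)
          warnings <- c(warnings, sprintf(
            "class '%s': only %d annotated pixels (requested %d); using all",
            lab, nrow(m), perClass))
        picked[[lab]] <- m
      } else {
        picked[[lab]] <- m[sample.int(nrow(m), perClass), , drop = FALSE]
      }
    }
  })
  # one feature map per image that contributed pixels
  allPicked <- do.call(rbind, picked)
  y <- rep(names(picked), vapply(picked, nrow, 0L))
  x <- matrix(0, nrow(allPicked), 18L)
  for (ii in unique(allPicked[, 1])) {
    fmap <- featureMap(images[[ii]], config)
    sel <- allPicked[, 1] == ii
    x[sel, ] <- .featuresAt(fmap, allPicked[sel, 2], allPicked[sel, 3])
    colnames(x) <- colnames(.featuresAt(fmap, 0L, 0L))
  }
  list(x = x, y = y, warnings = warnings)
}

#' Train an SVM pixel classifier
#'
#' Features are standardized by their training mean and SD (zero-variance
#' features get SD 1 and are flagged); a radial-basis-kernel SVM is fit with
#' one-vs-one decomposition, majority vote at prediction, and vote ties
#' broken by `labelSet` order. Training is deterministic: identical inputs
#' give identical models.
#'
#' @param x n x 18 feature matrix (from [sampleTrainingPixels]).
#' @param y character class labels, one per row of `x`.
#' @param labelSet ordered class names; must cover `unique(y)`. The order
#'   fixes the deterministic tie-break.
#' @param config the [FeatureConfig-class] the features came from.
#' @param cost SVM box constraint C (default 1).
#' @param gamma RBF kernel width; default `1 / ncol(x)` after
#'   standardization.
#' @param seed integer recorded in the training metadata (the fit itself is
#'   deterministic).
#' @param meta optional named list merged into the training metadata.
#' @return A [PixelModel-class].
#' @export
trainPixelModel <- function(x, y, labelSet = sort(unique(y)),
                            config = featureConfig(), cost = 1,
                            gamma = 1 / ncol(x), seed = 1L, meta = list()) {
  x <- as.matrix(x)
  if (!all(y %in% labelSet)) stop("labels outside labelSet: ",
                                  paste(setdiff(y, labelSet), collapse = ", "))
  present <- labelSet[labelSet %in% y]
  if (length(present) < 2L) stop("training needs at least 2 classes present")
  cnt <- table(factor(y, levels = present))
  if (any(cnt < 50L))
    stop("need >= 50 training vectors per class; short: ",
         paste(names(cnt)[cnt < 50L], collapse = ", "))
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  zero <- !is.finite(sd) | sd < 1e-12
  sd[zero] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sd, `/`)
  if (nrow(unique(xs)) < 2L)
    stop("degenerate training data: all feature vectors identical")
  yi <- match(y, present)
  pairs <- list()
  for (a in seq_len(length(present) - 1L)) {
    for (b in (a + 1L):length(present)) {
      sel <- yi == a | yi == b
      ypm <- ifelse(yi[sel] == a, 1, -1)
      fit <- .smoTrain(xs[sel, , drop = FALSE], ypm, cost, gamma,
                       eps = 1e-3, maxIter = 1000000L, cacheMb = 512)
      if (!fit$converged)
        warning("SMO did not converge for pair ", present[a], " vs ",
                present[b])
      svIdx <- which(fit$alpha > 1e-12)
      pairs[[length(pairs) + 1L]] <- list(
        classes = c(a, b),
        sv = xs[sel, , drop = FALSE][svIdx, , drop = FALSE],
        coef = fit$alpha[svIdx] * ypm[svIdx],
        rho = fit$rho)
    }
  }
  new("PixelModel", labelSet = present, featureConfig = config,
      scalerMean = unname(mu), scalerSd = unname(sd), zeroVariance = zero,
      pairs = pairs, gamma = gamma, cost = cost,
      trainingMeta = c(list(version = MODEL_FORMAT_VERSION, seed = seed,
                            nPerClass = as.list(as.integer(cnt))), meta))
}

# Predict class indices (into model@labelSet) for a standardized feature
# matrix; one-vs-one vote, ties broken by labelSet order.
.svmPredictIndex <- function(model, xs) {
  k <- length(model@labelSet)
  votes <- matrix(0L, nrow(xs), k)
  for (p in model@pairs) {
    dec <- .svmDecision(xs, p$sv, p$coef, p$rho, model@gamma)
    win <- ifelse(dec > 0, p$classes[1], p$classes[2])
    votes[cbind(seq_len(nrow(xs)), win)] <-
      votes[cbind(seq_len(nrow(xs)), win)] + 1L
  }
  max.col(votes, ties.method = "first")
}

#' Classify every pixel of an image
#'
#' Applies a trained [PixelModel-class] to an image. With a mask, only
#' masked pixels are classified and the rest receive the reserved
#' "unclassified" code 0. An optional prediction stride `s` classifies every
#' s-th pixel on a grid and fills the rest by nearest-neighbor; `s = 1`
#' (default, used by all validation) classifies every pixel. Images whose
#' edge exceeds `tileSize` are processed as overlapping tiles (overlap = the
#' feature window diameter) and stitched from tile interiors, which leaves
#' the result identical to the untiled computation.
#'
#' @param model a [PixelModel-class].
#' @param image a [RasterImage-class].
#' @param mask optional logical H x W matrix restricting classification.
#' @param stride prediction stride (default 1).
#' @param tileSize maximum edge length processed at once (default 8192 px).
#' @return A [LabelMap-class] with the model's `labelSet` as legend.
#' @export
predictLabels <- function(model, image, mask = NULL, stride = 1L,
                          tileSize = 8192L) {
  stopifnot(is(model, "PixelModel"), is(image, "RasterImage"))
  H <- dim(image@pixels)[1]; W <- dim(image@pixels)[2]
  if (!is.null(mask))
    stopifnot(is.logical(mask), nrow(mask) == H, ncol(mask) == W)
  if (H > tileSize || W > tileSize) {
    return(.predictTiled(model, image, mask, stride, tileSize))
  }
  fmap <- featureMap(image, model@featureConfig)
  labels <- matrix(0L, H, W)
  sel <- if (is.null(mask)) matrix(TRUE, H, W) else mask
  if (stride > 1L) {
    grid <- matrix(FALSE, H, W)
    grid[seq(1L, H, by = stride), seq(1L, W, by = stride)] <- TRUE
    sel <- sel & grid
  }
  w <- which(sel)
  if (length(w)) {
    rows <- (w - 1L) %% H; cols <- (w - 1L) %/% H
    xs <- .standardize(model, .featuresAt(fmap, rows, cols))
    labels[w] <- .svmPredictIndex(model, xs)
  }
  if (stride > 1L) {
    # nearest-neighbor fill from the stride grid
    gi <- seq(1L, H, by = stride); gj <- seq(1L, W, by = stride)
    ni <- gi[pmin(pmax(round((seq_len(H) - 1L) / stride) + 1L, 1L),
                  length(gi))]
    nj <- gj[pmin(pmax(round((seq_len(W) - 1L) / stride) + 1L, 1L),
                  length(gj))]
    filled <- labels[ni, nj, drop = FALSE]
    if (is.null(mask)) labels <- filled
    else { labels[mask] <- filled[mask]; labels[!mask] <- 0L }
  }
  labelMap(labels, model@labelSet, imageId = image@id)
}

.standardize <- function(model, x) {
  sweep(sweep(x, 2L, model@scalerMean), 2L, model@scalerSd, `/`)
}

.predictTiled <- function(model, image, mask, stride, tileSize) {
  H <- dim(image@pixels)[1]; W <- dim(image@pixels)[2]
  r <- model@featureConfig@windowRadius
  margin <- 2L * r + 2L   # window diameter; covers the edge-factor halo too
  labels <- matrix(0L, H, W)
  starts <- function(n) unique(c(seq(1L, n, by = tileSize)))
  for (i0 in starts(H)) for (j0 in starts(W)) {
    i1 <- min(H, i0 + tileSize - 1L); j1 <- min(W, j0 + tileSize - 1L)
    ei0 <- max(1L, i0 - margin); ei1 <- min(H, i1 + margin)
    ej0 <- max(1L, j0 - margin); ej1 <- min(W, j1 + margin)
    sub <- rasterImage(image@pixels[ei0:ei1, ej0:ej1, , drop = FALSE],
                       id = image@id)
    smask <- if (is.null(mask)) NULL else mask[ei0:ei1, ej0:ej1, drop = FALSE]
    lm <- predictLabels(model, sub, smask, stride = stride,
                        tileSize = .Machine$integer.max)
    labels[i0:i1, j0:j1] <-
      lm@labels[(i0 - ei0 + 1L):(i1 - ei0 + 1L),
                (j0 - ej0 + 1L):(j1 - ej0 + 1L), drop = FALSE]
  }
  labelMap(labels, model@labelSet, imageId = image@id)
}

#' Combine exclusion and classification models into a Main model
#'
#' The combined model runs the exclusion stage first; only pixels it labels
#' `tissue` are classified by the classification stage, so no background or
#' artefact pixel can ever receive an rbc/wbc/fibrin label.
#'
#' @param exclusion [PixelModel-class] over background / tissue / artefact.
#' @param classification [PixelModel-class] over rbc / wbc / fibrin.
#' @return A [MainModel-class].
#' @export
combineModels <- function(exclusion, classification) {
  stopifnot(is(exclusion, "PixelModel"), is(classification, "PixelModel"))
  if (!setequal(exclusion@labelSet, EXCLUSION_LABELS))
    stop("exclusion model must have exactly the labels {",
         paste(EXCLUSION_LABELS, collapse = ", "), "}; got {",
         paste(exclusion@labelSet, collapse = ", "), "}")
  if (!setequal(classification@labelSet, TISSUE_LABELS))
    stop("classification model must have exactly the labels {",
         paste(TISSUE_LABELS, collapse = ", "), "}")
  new("MainModel", exclusion = exclusion, classification = classification)
}

## --- model container format ----------------------------------------------
## Line 1: "ClotQuantModel <version> <kind>"
## Line 2: JSON header (label set, feature config, scaler, gamma, cost,
##         training metadata, binary block layout)
## Line 3: "BINARY <nbytes>"
## <nbytes> of little-endian doubles (per pair: support vectors
## column-major, coefficients, rho)
## Final line: "SHA256 <hex digest of the binary block>"

.pixelModelHeader <- function(m) {
  list(labelSet = m@labelSet,
       featureConfig = list(windowRadius = m@featureConfig@windowRadius),
       scalerMean = m@scalerMean, scalerSd = m@scalerSd,
       zeroVariance = m@zeroVariance, gamma = m@gamma, cost = m@cost,
       trainingMeta = m@trainingMeta,
       pairs = lapply(m@pairs, function(p)
         list(classes = p$classes, nsv = nrow(p$sv), d = ncol(p$sv))))
}

.pixelModelBinary <- function(m) {
  vals <- unlist(lapply(m@pairs, function(p)
    c(as.vector(p$sv), p$coef, p$rho)))
  writeBin(as.numeric(vals), raw(), size = 8L, endian = "little")
}

.serializeOne <- function(m, kind) {
  header <- jsonlite::toJSON(.pixelModelHeader(m), auto_unbox = TRUE,
                             digits = NA)
  bin <- .pixelModelBinary(m)
  c(charToRaw(paste0("ClotQuantModel ", MODEL_FORMAT_VERSION, " ", kind,
                     "\n")),
    charToRaw(paste0(header, "\n")),
    charToRaw(paste0("BINARY ", length(bin), "\n")),
    bin,
    charToRaw(paste0("\nSHA256 ",
                     digest::digest(bin, algo = "sha256", serialize = FALSE),
                     "\n")))
}

#' Save and load pixel classifiers
#'
#' Models are stored in a single-file container: a text header (format
#' version, kind, JSON metadata with label sets, feature configuration and
#' scaler) followed by a binary block holding the SVM state and a SHA-256
#' checksum of that block. Serialization is deterministic (two saves of the
#' same model are byte-identical) and the save/load round trip preserves
#' predictions exactly; a corrupted or truncated file fails to load with an
#' error naming the offending field.
#'
#' @param model a [PixelModel-class] or [MainModel-class].
#' @param path destination file.
#' @return `saveModel`: `path` invisibly. `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  if (is(model, "PixelModel")) {
    out <- .serializeOne(model, "pixel")
  } else if (is(model, "MainModel")) {
    ex <- .serializeOne(model@exclusion, "pixel")
    cl <- .serializeOne(model@classification, "pixel")
    head <- jsonlite::toJSON(list(exclusionBytes = length(ex),
                                  classificationBytes = length(cl)),
                             auto_unbox = TRUE)
    bin <- c(ex, cl)
    out <- c(charToRaw(paste0("ClotQuantModel ", MODEL_FORMAT_VERSION,
                              " main\n")),
             charToRaw(paste0(head, "\n")),
             charToRaw(paste0("BINARY ", length(bin), "\n")),
             bin,
             charToRaw(paste0("\nSHA256 ",
                              digest::digest(bin, algo = "sha256",
                                             serialize = FALSE), "\n")))
  } else stop("saveModel expects a PixelModel or MainModel")
  writeBin(out, path)
  invisible(path)
}

# Split one container blob into (magic words, header json, binary, rest ok).
.parseContainer <- function(raw, what = "model file") {
  nl <- which(raw == as.raw(10L))
  if (length(nl) < 3L) stop("truncated ", what, ": missing header lines")
  line <- function(k) rawToChar(raw[(c(0L, nl)[k] + 1L):(nl[k] - 1L)])
  magic <- strsplit(line(1L), " ", fixed = TRUE)[[1]]
  if (length(magic) != 3L || magic[1] != "ClotQuantModel")
    stop("not a ClotQuant model container: bad magic line")
  if (magic[2] != MODEL_FORMAT_VERSION)
    stop("model format version mismatch: file has '", magic[2],
         "', this package reads '", MODEL_FORMAT_VERSION, "'")
  header <- jsonlite::fromJSON(line(2L), simplifyVector = TRUE)
  blen <- strsplit(line(3L), " ", fixed = TRUE)[[1]]
  if (blen[1] != "BINARY") stop("corrupt ", what, ": missing BINARY marker")
  nbytes <- as.integer(blen[2])
  binStart <- nl[3L] + 1L
  if (length(raw) < binStart + nbytes - 1L)
    stop("truncated ", what, ": binary block shorter than declared")
  bin <- raw[binStart:(binStart + nbytes - 1L)]
  tail <- rawToChar(raw[(binStart + nbytes):length(raw)])
  sha <- sub("^\\s*SHA256 ([0-9a-f]{64})\\s*$", "\\1", tail)
  if (identical(sha, tail)) stop("corrupt ", what, ": missing SHA256 trailer")
  if (!identical(sha, digest::digest(bin, algo = "sha256",
                                     serialize = FALSE)))
    stop("integrity check failed for ", what,
         ": classifier_state checksum mismatch")
  list(kind = magic[3], header = header, bin = bin)
}

.deserializeOne <- function(parsed) {
  h <- parsed$header
  vals <- readBin(parsed$bin, "numeric", n = length(parsed$bin) / 8L,
                  size = 8L, endian = "little")
  pairsMeta <- h$pairs
  getMeta <- function(i, f) {
    if (is.data.frame(pairsMeta)) pairsMeta[[f]][[i]]
    else pairsMeta[[i]][[f]]
  }
  npairs <- if (is.data.frame(pairsMeta)) nrow(pairsMeta)
            else length(pairsMeta)
  pairs <- vector("list", npairs)
  off <- 0L
  for (i in seq_len(npairs)) {
    nsv <- as.integer(getMeta(i, "nsv")); d <- as.integer(getMeta(i, "d"))
    need <- nsv * d + nsv + 1L
    if (off + need > length(vals))
      stop("corrupt model file: binary block shorter than pair layout")
    sv <- matrix(vals[(off + 1L):(off + nsv * d)], nsv, d)
    coef <- vals[(off + nsv * d + 1L):(off + nsv * d + nsv)]
    rho <- vals[off + need]
    off <- off + need
    pairs[[i]] <- list(classes = as.integer(getMeta(i, "classes")),
                       sv = sv, coef = coef, rho = rho)
  }
  new("PixelModel", labelSet = as.character(h$labelSet),
      featureConfig = featureConfig(h$featureConfig$windowRadius),
      scalerMean = as.numeric(h$scalerMean),
      scalerSd = as.numeric(h$scalerSd),
      zeroVariance = as.logical(h$zeroVariance), pairs = pairs,
      gamma = as.numeric(h$gamma), cost = as.numeric(h$cost),
      trainingMeta = as.list(h$trainingMeta))
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  parsed <- .parseContainer(raw)
  if (parsed$kind == "pixel") return(.deserializeOne(parsed))
  if (parsed$kind != "main") stop("unknown model kind: ", parsed$kind)
  n1 <- as.integer(parsed$header$exclusionBytes)
  ex <- .deserializeOne(.parseContainer(parsed$bin[seq_len(n1)],
                                        "embedded exclusion model"))
  cl <- .deserializeOne(.parseContainer(parsed$bin[(n1 + 1L):length(parsed$bin)],
                                        "embedded classification model"))
  combineModels(ex, cl)
}
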