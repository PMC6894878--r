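# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force or closed form, never
# by calling the package functions they check.

randomTestImage <- function(seed, h = 16, w = 16) {
  set.seed(seed)
  ClotQuant::rasterImage(array(sample(0:255, h * w * 3, TRUE), c(h, w, 3)),
                         id = paste0("rand-", seed))
}

# Scalar even-odd point-in-polygon by explicit crossing count.
oraclePointInPolygon <- function(pr, pc, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    ri <- poly[i, 1]; ci <- poly[i, 2]
    rj <- poly[j, 1]; cj <- poly[j, 2]
    if ((ri > pr) != (rj > pr)) {
      xint <- (cj - ci) * (pr - ri) / (rj - ri) + ci
      if (pc < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Mid-rank + explicit Pearson-on-ranks Spearman oracle.
oracleSpearman <- function(x, y) {
  midrank <- function(v) vapply(v, function(a)
    sum(v < a) + (sum(v == a) + 1) / 2, 0)
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Closed form for a 2x2 table.
oracleChi2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# A small annotated synthetic world shared by several model tests.
smallAnnotatedSet <- function(seed = 42, n = 3) {
  ClotQuant::generateAnnotatedSet(
    ClotQuant::synthParams(height = 128L, width = 128L,
                           targetFractions = c(rbc = 0.5, wbc = 0.1,
                                               fibrin = 0.4),
                           nArtefactFolds = 1L, seed = seed),
    nImages = n, pixelsPerClass = 600L)
}

trainSmallModels <- function(set, perClass = 500L, radius = 2L) {
  imgs <- lapply(set, `[[`, "image")
  regs <- do.call(c, lapply(set, `[[`, "regions"))
  cfg <- ClotQuant::featureConfig(radius)
  ex <- ClotQuant::sampleTrainingPixels(imgs, ClotQuant::relabelRegions(regs),
                                        perClass = perClass, seed = 1L,
                                        config = cfg)
  tis <- Filter(function(r) r@label %in% c("rbc", "wbc", "fibrin"), regs)
  cl <- ClotQuant::sampleTrainingPixels(imgs, tis, perClass = perClass,
                                        seed = 1L, config = cfg)
  list(
    exclusion = ClotQuant::trainPixelModel(
      ex$x, ex$y, c("background", "tissue", "artefact"), config = cfg),
    classification = ClotQuant::trainPixelModel(
      cl$x, cl$y, c("rbc", "wbc", "fibrin"), config = cfg),
    samples = list(exclusion = ex, classification = cl))
}

# Minimal independent TIFF byte-builder (little-endian, one strip), used to
# exercise the package's reader against bytes it did not write itself.
buildTinyTiff <- function(values16, h, w, secondIfd = NULL) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                              endian = "little")
  entry <- function(tag, typ, cnt, val) c(u16(tag), u16(typ), u32(cnt),
                                          if (typ == 3) c(u16(val), u16(0))
                                          else u32(val))
  mkIfd <- function(vals, h, w, dataOff, nextOff) {
    tags <- list(c(256, 4, 1, w), c(257, 4, 1, h), c(258, 3, 1, 16),
                 c(259, 3, 1, 1), c(262, 3, 1, 1), c(273, 4, 1, dataOff),
                 c(277, 3, 1, 1), c(278, 4, 1, h),
                 c(279, 4, 1, 2 * h * w))
    c(u16(length(tags)),
      do.call(c, lapply(tags, function(t) entry(t[1], t[2], t[3], t[4]))),
      u32(nextOff))
  }
  ifdLen <- 2 + 12 * 9 + 4
  data1 <- writeBin(as.integer(values16), raw(), size = 2, endian = "little")
  if (is.null(secondIfd)) {
    c(as.raw(c(0x49, 0x49)), u16(42), u32(8),
      mkIfd(values16, h, w, 8 + ifdLen, 0), data1)
  } else {
    # header | IFD1 | IFD2 | data1 | data2
    off1 <- 8 + 2 * ifdLen
    off2 <- off1 + length(data1)
    data2 <- writeBin(as.integer(secondIfd$values16), raw(), size = 2,
                      endian = "little")
    c(as.raw(c(0x49, 0x49)), u16(42), u32(8),
      mkIfd(values16, h, w, off1, 8 + ifdLen),
      mkIfd(secondIfd$values16, secondIfd$h, secondIfd$w, off2, 0),
      data1, data2)
  }
}
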