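# Color-threshold comparator: bounds derivation, matching rules,
# monotonicity and conservation.

pureFieldImage <- function() {
  # three vertical color fields: 60% (200,60,70), 10% (90,60,150),
  # 30% (235,170,185) on a 100x100 image
  px <- array(0L, c(100, 100, 3))
  cols <- list(rbc = c(200, 60, 70), wbc = c(90, 60, 150),
               fibrin = c(235, 170, 185))
  px[, 1:60, ] <- rep(cols$rbc, each = 100 * 60)
  px[, 61:70, ] <- rep(cols$wbc, each = 100 * 10)
  px[, 71:100, ] <- rep(cols$fibrin, each = 100 * 30)
  rasterImage(px, id = "fields")
}

test_that("thresholds derive from region min/max with tolerance", {
  img <- rasterImage(array(rep(c(200L, 60L, 70L), each = 64), c(8, 8, 3)),
                     id = "const")
  reg <- annotationRegion("rbc", "rectangle", rbind(c(1, 1), c(4, 4)))
  thr <- thresholdFromRegion(img, reg, tolerance = 0)
  expect_equal(thr@low, c(200, 60, 70))
  expect_equal(thr@high, c(200, 60, 70))
  # random region: bounds equal the brute-force per-channel scan
  rimg <- randomTestImage(33, 20, 20)
  reg2 <- annotationRegion("x", "rectangle", rbind(c(2, 3), c(10, 12)))
  thr2 <- thresholdFromRegion(rimg, reg2, tolerance = 5)
  mask <- rasterizeRegion(reg2, c(20, 20))
  for (ch in 1:3) {
    v <- imagePixels(rimg)[, , ch][mask]
    expect_equal(thr2@low[ch], max(0, min(v) - 5))
    expect_equal(thr2@high[ch], min(255, max(v) + 5))
  }
})

test_that("disjoint exact thresholds quantify pure fields exactly", {
  img <- pureFieldImage()
  thr <- list(
    new("ColorThreshold", label = "rbc", low = c(195, 55, 65),
        high = c(205, 65, 75)),
    new("ColorThreshold", label = "wbc", low = c(85, 55, 145),
        high = c(95, 65, 155)),
    new("ColorThreshold", label = "fibrin", low = c(230, 165, 180),
        high = c(240, 175, 190)))
  q <- thresholdQuantify(img, thr, denominator = "tissue")
  expect_equal(unname(q$pct), c(60, 10, 30))
  expect_equal(q$pct_unmatched, 0)
  # whole-image denominator on the same slide gives the same numbers here
  qw <- thresholdQuantify(img, thr, denominator = "whole_image")
  expect_equal(unname(qw$pct), c(60, 10, 30))
})

test_that("multi-match pixels resolve to the nearest centroid", {
  px <- array(rep(c(120L, 100L, 100L), each = 16), c(4, 4, 3))
  img <- rasterImage(px, id = "amb")
  thr <- list(
    new("ColorThreshold", label = "rbc", low = c(110, 90, 90),
        high = c(130, 110, 110)),   # centroid (120,100,100): exact match
    new("ColorThreshold", label = "wbc", low = c(0, 0, 0),
        high = c(20, 20, 20)),
    new("ColorThreshold", label = "fibrin", low = c(100, 80, 80),
        high = c(200, 180, 180)))   # also matches, centroid farther
  q <- thresholdQuantify(img, thr, denominator = "tissue")
  expect_equal(unname(q$counts["rbc"]), 16)
  expect_equal(unname(q$counts["fibrin"]), 0)
})

test_that("cropping, conservation and monotonicity hold", {
  img <- pureFieldImage()
  thr <- list(
    new("ColorThreshold", label = "rbc", low = c(195, 55, 65),
        high = c(205, 65, 75)),
    new("ColorThreshold", label = "wbc", low = c(85, 55, 145),
        high = c(95, 65, 155)),
    new("ColorThreshold", label = "fibrin", low = c(230, 165, 180),
        high = c(240, 175, 190)))
  crop <- list(annotationRegion("artefact", "rectangle",
                                rbind(c(0, 0), c(99, 9)), "fields"))
  q <- thresholdQuantify(img, thr, crop, denominator = "whole_image")
  expect_equal(unname(sum(q$counts)), 100 * 100)
  expect_equal(unname(q$counts["cropped"]), 1000)
  # narrowing rbc bounds cannot increase the rbc count
  thrNarrow <- thr
  thrNarrow[[1]]@low <- thrNarrow[[1]]@low + c(10, 0, 0)
  qn <- thresholdQuantify(img, thrNarrow, crop, denominator = "whole_image")
  expect_lte(qn$counts[["rbc"]], q$counts[["rbc"]])
  # identical thresholds for two classes are a configuration error
  thrDup <- thr
  thrDup[[2]] <- new("ColorThreshold", label = "wbc", low = thr[[1]]@low,
                     high = thr[[1]]@high)
  expect_error(thresholdQuantify(img, thrDup), "identical thresholds")
})
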