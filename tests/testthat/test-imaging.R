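# Raster I/O and annotation-region rasterization.

test_that("PNG and TIFF round trips are bit-exact and grayscale replicates", {
  img <- randomTestImage(7, 32, 32)
  for (ext in c(".png", ".tif")) {
    p <- tempfile(fileext = ext)
    writeImage(img, p)
    back <- readImage(p, id = imageId(img))
    expect_identical(imagePixels(back), imagePixels(img))
  }
  # constant-value PNG reads back as written
  p <- tempfile(fileext = ".png")
  writeImage(rasterImage(array(128L, c(64, 64, 3)), id = "c"), p)
  expect_true(all(imagePixels(readImage(p)) == 128L))
  # grayscale input replicates to three identical channels
  g <- tempfile(fileext = ".png")
  set.seed(3)
  png::writePNG(matrix(runif(64), 8, 8), g)
  px <- imagePixels(readImage(g))
  expect_identical(px[, , 1], px[, , 2])
  expect_identical(px[, , 1], px[, , 3])
})

test_that("16-bit and multi-level TIFF follow the rescale and level rules", {
  vals <- matrix(c(0L, 257L, 65535L, 51400L), 2, 2)
  # row-major strip layout: transpose when flattening
  bytes <- buildTinyTiff(as.vector(t(vals)), 2, 2,
                         secondIfd = list(values16 = 65535L, h = 1, w = 1))
  p <- tempfile(fileext = ".tif")
  writeBin(bytes, p)
  lvl1 <- imagePixels(readImage(p))
  expect_equal(lvl1[, , 1], round(vals / 257))   # 16-bit -> 8-bit rescale
  lvl2 <- imagePixels(readImage(p, level = 2))
  expect_equal(dim(lvl2), c(1L, 1L, 3L))
  expect_equal(lvl2[1, 1, 1], 255)
  expect_error(readImage(p, level = 3), "fewer than 3 levels")
})

test_that("unreadable or unsupported inputs fail with the path named", {
  expect_error(readImage("/nonexistent/file.png"), "no such file")
  p <- tempfile(fileext = ".png")
  writeBin(as.raw(1:10), p)
  expect_error(readImage(p), "not PNG or TIFF")
})

test_that("rasterizeRegion handles rectangles, polygons and ellipses", {
  # axis-aligned rectangle rows 0-1, cols 0-1 on a 4x4 extent: 4 pixels
  rect <- annotationRegion("x", "rectangle", rbind(c(0, 0), c(1, 1)))
  m <- rasterizeRegion(rect, c(4, 4))
  expect_equal(sum(m), 4)
  expect_true(all(m[1:2, 1:2]))

  # triangle matches the brute-force even-odd center test per pixel
  tri <- rbind(c(0, 0), c(0, 3), c(3, 0))
  mt <- rasterizeRegion(annotationRegion("x", "polygon", tri), c(4, 4))
  for (i in 0:3) for (j in 0:3)
    expect_identical(mt[i + 1, j + 1], oraclePointInPolygon(i, j, tri),
                     info = sprintf("pixel (%d,%d)", i, j))

  # sub-pixel ellipse contains only its center pixel
  ell <- annotationRegion("x", "ellipse", rbind(c(2, 2), c(0.6, 0.6)))
  me <- rasterizeRegion(ell, c(5, 5))
  expect_equal(sum(me), 1)
  expect_true(me[3, 3])

  expect_error(
    rasterizeRegion(annotationRegion("x", "rectangle",
                                     rbind(c(10, 10), c(12, 12))), c(4, 4)),
    "empty region")
})

test_that("rasterization is translation invariant and disjointness holds", {
  set.seed(11)
  poly <- cbind(runif(5, 1, 8), runif(5, 1, 8))
  m0 <- rasterizeRegion(annotationRegion("x", "polygon", poly), c(12, 12))
  for (shift in list(c(1, 2), c(3, 0))) {
    ms <- rasterizeRegion(
      annotationRegion("x", "polygon", sweep(poly, 2, shift, `+`)),
      c(12 + shift[1], 12 + shift[2]))
    expect_equal(sum(ms), sum(m0))
  }
  a <- rasterizeRegion(annotationRegion("a", "rectangle",
                                        rbind(c(0, 0), c(3, 3))), c(10, 10))
  b <- rasterizeRegion(annotationRegion("b", "rectangle",
                                        rbind(c(5, 5), c(8, 8))), c(10, 10))
  expect_false(any(a & b))
})

test_that("annotation files round trip", {
  regs <- list(
    annotationRegion("rbc", "rectangle", rbind(c(0, 0), c(4, 6)), "img1"),
    annotationRegion("fibrin", "polygon",
                     rbind(c(0.5, 1), c(2, 8.25), c(7, 3)), "img1"),
    annotationRegion("wbc", "ellipse", rbind(c(5, 5), c(2, 3)), "img2"))
  p <- tempfile(fileext = ".tsv")
  writeAnnotations(regs, p)
  back <- readAnnotations(p)
  expect_length(back, 3)
  for (i in seq_along(regs)) {
    expect_equal(back[[i]]@label, regs[[i]]@label)
    expect_equal(back[[i]]@shape, regs[[i]]@shape)
    expect_equal(back[[i]]@coords, regs[[i]]@coords)
    expect_equal(back[[i]]@imageId, regs[[i]]@imageId)
  }
})

test_that("label-map PNG export uses the documented palette", {
  lm <- labelMap(matrix(c(1L, 2L, 3L, 5L), 2, 2),
                 c("background", "artefact", "rbc", "wbc", "fibrin"), "x")
  p <- tempfile(fileext = ".png")
  writeLabelMapPng(lm, p)
  px <- png::readPNG(p) * 255
  expect_equal(px[1, 1, ], c(60, 90, 220))   # background blue
  expect_equal(px[2, 1, ], c(0, 0, 0))       # artefact black
})
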