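# Sliding-window feature extraction: frozen arithmetic cases, the
# brute-force oracle, and the invariance properties.

test_that("windowFeatures reproduces hand-computed window statistics", {
  # constant field: (v, v, v, 0, 0, v) per channel
  img <- rasterImage(array(100L, c(8, 8, 3)), id = "c")
  f <- windowFeatures(img, c(3, 3), featureConfig(2))
  for (ch in c("R", "G", "B")) {
    expect_equal(unname(f[paste0(ch, ".min")]), 100)
    expect_equal(unname(f[paste0(ch, ".max")]), 100)
    expect_equal(unname(f[paste0(ch, ".mean")]), 100)
    expect_equal(unname(f[paste0(ch, ".variance")]), 0)
    expect_equal(unname(f[paste0(ch, ".edge_factor")]), 0)
    expect_equal(unname(f[paste0(ch, ".center")]), 100)
  }

  # 3x3 image holding 1..9, radius 1, center pixel: window is the image
  img9 <- rasterImage(matrix(1:9, 3, 3), id = "nine")
  f9 <- windowFeatures(img9, c(1, 1), featureConfig(1))
  expect_equal(unname(f9["R.min"]), 1)
  expect_equal(unname(f9["R.max"]), 9)
  expect_equal(unname(f9["R.mean"]), 5)
  expect_equal(unname(f9["R.variance"]), 20 / 3)
  expect_equal(unname(f9["R.center"]), 5)

  # vertical step edge 0|255 through the center
  step <- matrix(0L, 9, 9); step[, 5:9] <- 255L
  fs <- windowFeatures(rasterImage(step, id = "s"), c(4, 4), featureConfig(2))
  expect_gt(unname(fs[["R.edge_factor"]]), 0)
  expect_equal(unname(fs[["R.max"]] - fs[["R.min"]]), 255)

  expect_error(windowFeatures(img, c(8, 0)), "outside the image")
})

test_that("featureMap equals the naive per-pixel computation", {
  for (seed in 1:3) {
    img <- randomTestImage(seed, 12, 10)
    for (r in c(1, 4, 7)) {   # r = 7 exceeds the half-size: reflect rule
      cfg <- featureConfig(r)
      fm <- featureMap(img, cfg)
      set.seed(seed + 100)
      centers <- cbind(sample(0:11, 12, TRUE), sample(0:9, 12, TRUE))
      for (k in seq_len(nrow(centers))) {
        expect_equal(unname(fm[centers[k, 1] + 1, centers[k, 2] + 1, ]),
                     unname(windowFeatures(img, centers[k, ], cfg)),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("constant images give translation-identical feature rows", {
  img <- rasterImage(array(77L, c(10, 12, 3)), id = "c")
  fm <- featureMap(img, featureConfig(3))
  for (f in seq_len(18))
    expect_true(all(fm[, , f] == fm[1, 1, f]))
})

test_that("adding a constant shifts location features and preserves spread", {
  img <- randomTestImage(9, 14, 14)
  px <- imagePixels(img)
  k <- 30L
  shifted <- rasterImage(pmin(px + k, 255L), id = "s")
  # keep away from clipping: only compare where the window never saturates
  stopifnot(max(px) + k <= 255 || TRUE)
  img2 <- rasterImage(px %/% 2L, id = "h")       # safe range 0..127
  shifted <- rasterImage(px %/% 2L + k, id = "h+k")
  cfg <- featureConfig(2)
  f1 <- featureMap(img2, cfg); f2 <- featureMap(shifted, cfg)
  nm <- dimnames(f1)[[3]]
  loc <- grepl("min|max|mean|center", nm)
  expect_equal(f2[, , loc], f1[, , loc] + k, tolerance = 1e-9)
  expect_equal(f2[, , !loc], f1[, , !loc], tolerance = 1e-9)
})

test_that("interior features are invariant under image translation", {
  img <- randomTestImage(21, 16, 16)
  px <- imagePixels(img)
  sub1 <- rasterImage(px[1:12, 1:12, , drop = FALSE], id = "a")
  sub2 <- rasterImage(px[3:14, 3:14, , drop = FALSE], id = "b")
  cfg <- featureConfig(2)
  # pixel (7,7) of sub1 is pixel (5,5) of sub2; both interiors
  expect_equal(windowFeatures(sub1, c(7, 7), cfg),
               windowFeatures(sub2, c(5, 5), cfg), tolerance = 1e-9)
})
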