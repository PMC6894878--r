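# Synthetic slide generator: determinism, fraction control, ground-truth
# integrity, and annotation purity.

test_that("generation is deterministic and fraction-controlled", {
  p <- synthParams(height = 512L, width = 512L,
                   targetFractions = c(rbc = 0.6, wbc = 0.1, fibrin = 0.3),
                   seed = 5L)
  s1 <- generateClotSlide(p)
  s2 <- generateClotSlide(p)
  expect_identical(imagePixels(s1$image), imagePixels(s2$image))
  expect_identical(labelCodes(s1$truth), labelCodes(s2$truth))
  # realized fractions within 3 percentage points of targets
  expect_lt(max(abs(s1$fractions - c(0.6, 0.1, 0.3))), 0.03)
  expect_equal(sum(s1$fractions), 1)
})

test_that("degenerate composition and absent classes behave as stated", {
  p <- synthParams(height = 160L, width = 160L,
                   targetFractions = c(rbc = 1, wbc = 0, fibrin = 0),
                   seed = 2L)
  s <- generateClotSlide(p)
  expect_equal(unname(s$fractions["rbc"]), 1)
  lab <- labelCodes(s$truth)
  expect_equal(sum(lab == 4L) + sum(lab == 5L), 0)  # no wbc, no fibrin
})

test_that("ground truth never assigns tissue classes outside tissue", {
  p <- synthParams(height = 200L, width = 200L, nArtefactFolds = 2L,
                   seed = 9L)
  s <- generateClotSlide(p)
  lab <- labelCodes(s$truth)
  expect_setequal(unique(as.vector(lab)), 1:5)
  # fold pixels exist and fractions still sum to 1 over remaining tissue
  expect_gt(sum(lab == 2L), 0)
  expect_equal(sum(s$fractions), 1)
})

test_that("noise level changes the image but not the ground truth", {
  p1 <- synthParams(seed = 4L, noiseSd = 4)
  p2 <- synthParams(seed = 4L, noiseSd = 20)
  s1 <- generateClotSlide(p1); s2 <- generateClotSlide(p2)
  expect_identical(labelCodes(s1$truth), labelCodes(s2$truth))
  expect_false(identical(imagePixels(s1$image), imagePixels(s2$image)))
})

test_that("annotated sets cover present classes with pure regions", {
  set <- generateAnnotatedSet(synthParams(height = 160L, width = 160L,
                                          nArtefactFolds = 1L, seed = 31L),
                              nImages = 5L, pixelsPerClass = 400L)
  expect_length(set, 5)
  for (s in set) {
    labs <- vapply(s$regions, function(r) r@label, "")
    expect_setequal(unique(labs),
                    c("background", "artefact", "rbc", "wbc", "fibrin"))
    # every region is single-class in ground truth (100% purity)
    truth <- labelCodes(s$truth)
    for (r in s$regions) {
      m <- rasterizeRegion(r, dim(truth))
      codes <- unique(truth[m])
      expect_length(codes, 1)
      expect_equal(ClotQuant:::ALL_LABELS[codes], r@label)
    }
  }
})

test_that("a fold-free generator emits no artefact regions", {
  set <- generateAnnotatedSet(synthParams(height = 160L, width = 160L,
                                          nArtefactFolds = 0L, seed = 8L),
                              nImages = 1L, pixelsPerClass = 300L)
  labs <- vapply(set[[1]]$regions, function(r) r@label, "")
  expect_false("artefact" %in% labs)
  expect_true(any(grepl("artefact.*absent", set[[1]]$warnings)))
})

test_that("invalid parameters are rejected", {
  expect_error(synthParams(targetFractions = c(rbc = 0.5, wbc = 0.5,
                                               fibrin = 0.5)),
               "sum to 1")
  expect_error(synthParams(height = 20L, width = 20L), "1000")
  expect_error(synthParams(backgroundFraction = 1), "\\[0, 1\\)")
})
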