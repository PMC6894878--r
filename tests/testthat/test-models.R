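# SVM pixel classifiers: sampling, training, prediction, serialization.

set.seed(1)
gauss2 <- local({
  n <- 500
  x <- rbind(matrix(rnorm(n * 4, 0), n),
             matrix(rnorm(n * 4, 10), n))   # 10 SD separation
  list(x = x, y = rep(c("a", "b"), each = n))
})

test_that("well-separated clusters train to 100% training accuracy", {
  m <- trainPixelModel(gauss2$x, gauss2$y, c("a", "b"), gamma = 0.25)
  pred <- c("a", "b")[ClotQuant:::.svmPredictIndex(
    m, ClotQuant:::.standardize(m, gauss2$x))]
  expect_equal(mean(pred == gauss2$y), 1)
})

test_that("training preconditions are enforced", {
  expect_error(trainPixelModel(gauss2$x, rep("a", nrow(gauss2$x)), "a"),
               "at least 2 classes")
  expect_error(trainPixelModel(gauss2$x[1:60, ],
                               rep(c("a", "b"), c(55, 5)), c("a", "b")),
               ">= 50 training vectors")
  xdeg <- matrix(1, 200, 3)
  expect_error(trainPixelModel(xdeg, rep(c("a", "b"), 100), c("a", "b")),
               "degenerate")
})

test_that("standardization yields mean 0 / SD 1 on training features", {
  m <- trainPixelModel(gauss2$x, gauss2$y, c("a", "b"))
  xs <- ClotQuant:::.standardize(m, gauss2$x)
  expect_lt(max(abs(colMeans(xs))), 1e-9)
  expect_lt(max(abs(apply(xs, 2, sd) - 1)), 1e-9)
})

test_that("decisions agree with an independent SVM implementation", {
  # scikit-learn (same C, gamma, RBF kernel, one-vs-one) as external oracle
  set.seed(7)
  n <- 150
  x <- rbind(matrix(rnorm(n * 2, -1.5), n), matrix(rnorm(n * 2, 1.5), n),
             cbind(rnorm(n, -1.5), rnorm(n, 1.5) + 3))
  y <- rep(c("a", "b", "c"), each = n)
  m <- trainPixelModel(x, y, c("a", "b", "c"), gamma = 0.5)
  xs <- ClotQuant:::.standardize(m, x)
  ours <- c("a", "b", "c")[ClotQuant:::.svmPredictIndex(m, xs)]
  dir <- tempfile(); dir.create(dir)
  write.csv(data.frame(xs, y = y), file.path(dir, "d.csv"), row.names = FALSE)
  script <- file.path(dir, "svc.py")
  writeLines(c(
    "import pandas as pd, sys",
    "from sklearn.svm import SVC",
    sprintf("d = pd.read_csv(r'%s')", file.path(dir, "d.csv")),
    "X = d[['X1','X2']].values; y = d['y'].values",
    "clf = SVC(C=1.0, kernel='rbf', gamma=0.5).fit(X, y)",
    "pd.Series(clf.predict(X)).to_csv(sys.argv[1], index=False, header=False)"
  ), script)
  outfile <- file.path(dir, "pred.csv")
  status <- system2("python", c(script, outfile), stdout = FALSE,
                    stderr = FALSE)
  expect_equal(status, 0L)
  theirs <- readLines(outfile)
  expect_gte(mean(ours == theirs), 0.98)
})

test_that("sampleTrainingPixels balances, warns on shortfall, is seeded", {
  set <- smallAnnotatedSet(seed = 13, n = 2)
  imgs <- lapply(set, `[[`, "image")
  regs <- do.call(c, lapply(set, `[[`, "regions"))
  tis <- Filter(function(r) r@label %in% c("rbc", "wbc", "fibrin"), regs)
  s1 <- sampleTrainingPixels(imgs, tis, perClass = 200L, seed = 5L,
                             config = featureConfig(2))
  expect_equal(as.vector(table(s1$y)), rep(200L, 3))
  s2 <- sampleTrainingPixels(imgs, tis, perClass = 200L, seed = 5L,
                             config = featureConfig(2))
  expect_identical(s1$x, s2$x)
  # per_class above availability: all pixels used plus a warning record
  s3 <- sampleTrainingPixels(imgs, tis, perClass = 10^6, seed = 5L,
                             config = featureConfig(2))
  expect_true(any(grepl("using all", s3$warnings)))
  expect_lt(nrow(s3$x), 3 * 10^6)
  expect_error(
    sampleTrainingPixels(imgs, list(annotationRegion("ghost", "rectangle",
                                                     rbind(c(0, 0), c(2, 2)),
                                                     "not-an-image")),
                         perClass = 10L),
    "zero annotated pixels")
})

test_that("models predict annotated pixels of their training set accurately", {
  set <- smallAnnotatedSet(seed = 42, n = 3)
  models <- trainSmallModels(set)
  cl <- models$samples$classification
  pred <- c("rbc", "wbc", "fibrin")[ClotQuant:::.svmPredictIndex(
    models$classification,
    ClotQuant:::.standardize(models$classification, cl$x))]
  expect_gte(mean(pred == cl$y), 0.99)
})

test_that("prediction is deterministic, maskable and tiling-invariant", {
  set <- smallAnnotatedSet(seed = 42, n = 3)
  models <- trainSmallModels(set)
  img <- set[[1]]$image
  lm1 <- predictLabels(models$exclusion, img)
  lm2 <- predictLabels(models$exclusion, img)
  expect_identical(labelCodes(lm1), labelCodes(lm2))
  # empty mask: everything unclassified
  H <- dim(imagePixels(img))[1]; W <- dim(imagePixels(img))[2]
  lme <- predictLabels(models$exclusion, img, mask = matrix(FALSE, H, W))
  expect_true(all(labelCodes(lme) == 0L))
  # forced tiling reproduces the untiled labels exactly
  lmt <- predictLabels(models$exclusion, img, tileSize = 48L)
  expect_identical(labelCodes(lmt), labelCodes(lm1))
  # stride > 1 still labels every pixel
  lms <- predictLabels(models$exclusion, img, stride = 4L)
  expect_true(all(labelCodes(lms) > 0L))
})

test_that("save/load round trip preserves predictions and bytes", {
  set <- smallAnnotatedSet(seed = 42, n = 3)
  models <- trainSmallModels(set)
  img <- set[[2]]$image
  p1 <- tempfile(fileext = ".model"); p2 <- tempfile(fileext = ".model")
  saveModel(models$exclusion, p1)
  saveModel(models$exclusion, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))  # deterministic bytes
  back <- loadModel(p1)
  expect_identical(labelCodes(predictLabels(back, img)),
                   labelCodes(predictLabels(models$exclusion, img)))
  # main model container
  main <- combineModels(models$exclusion, models$classification)
  pm <- tempfile(fileext = ".model")
  saveModel(main, pm)
  mback <- loadModel(pm)
  expect_identical(labelCodes(applyMainModel(mback, img)),
                   labelCodes(applyMainModel(main, img)))
  # corrupting one byte of the classifier state must fail loudly
  raw <- readBin(p1, "raw", file.size(p1))
  mark <- length(raw) - 80L   # inside the binary block
  raw[mark] <- xor(raw[mark], as.raw(0xff))
  pbad <- tempfile(fileext = ".model")
  writeBin(raw, pbad)
  expect_error(loadModel(pbad), "checksum|truncated|corrupt")
  # truncation must fail loudly too
  ptrunc <- tempfile(fileext = ".model")
  writeBin(readBin(p1, "raw", file.size(p1))[1:100], ptrunc)
  expect_error(loadModel(ptrunc), "truncated|corrupt")
})

test_that("combineModels validates label sets", {
  set <- smallAnnotatedSet(seed = 42, n = 3)
  models <- trainSmallModels(set)
  expect_s4_class(combineModels(models$exclusion, models$classification),
                  "MainModel")
  expect_error(combineModels(models$classification, models$classification),
               "exclusion model")
  # exclusion model missing a class is rejected
  ex2 <- models$samples$exclusion
  keep <- ex2$y != "artefact"
  noArt <- trainPixelModel(ex2$x[keep, ], ex2$y[keep],
                           c("background", "tissue"),
                           config = featureConfig(2))
  expect_error(combineModels(noArt, models$classification),
               "exclusion model")
})
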