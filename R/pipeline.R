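## Pipeline orchestration in the standard operating order:
## synth/annotate -> train exclusion -> train classification -> combine ->
## batch quantify -> threshold comparator -> agreement statistics.
## Logs go to standard error with timestamps; primary outputs are files
## under the configured output directory plus the returned tables.

.configSchema <- function() list(
  seed = NULL, out_dir = NULL, stages = NULL, model_path = NULL,
  images_dir = NULL, stride = NULL, denominator = NULL, tolerance = NULL,
  per_class = NULL, log = NULL,
  feature = list(window_radius = NULL),
  svm = list(cost = NULL, gamma = NULL),
  synth = list(n_train = NULL, n_val = NULL, n_test = NULL, height = NULL,
               width = NULL, background_fraction = NULL, n_folds = NULL,
               noise_sd = NULL, pixels_per_class = NULL,
               rbc_range = NULL, wbc_fraction = NULL))

.checkConfigKeys <- function(config, schema, prefix = "") {
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(schema[[k]]) && !is.null(config[[k]]))
      .checkConfigKeys(config[[k]], schema[[k]], paste0(prefix, k, "."))
  }
}

.mergeDefaults <- function(config, defaults) {
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      config[[k]] <- .mergeDefaults(config[[k]], defaults[[k]])
  }
  config
}

.log <- function(enabled, fmt, ...) {
  if (enabled)
    message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...)))
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys error before any computation; omitted keys get documented
#' defaults. The configuration round-trips losslessly through JSON.
#'
#' @param config named list (possibly nested), or a path to a JSON config
#'   file.
#' @return The completed configuration list.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  .checkConfigKeys(config, .configSchema())
  defaults <- list(
    seed = 1L, out_dir = tempfile("clotquant-run-"),
    stages = c("synth", "train", "combine", "quantify", "threshold",
               "stats"),
    stride = 1L, denominator = "tissue", tolerance = 0, per_class = 2000L,
    log = TRUE,
    feature = list(window_radius = 4L),
    svm = list(cost = 1, gamma = NA),
    synth = list(n_train = 5L, n_val = 5L, n_test = 10L, height = 192L,
                 width = 192L, background_fraction = 0.3, n_folds = 2L,
                 noise_sd = 8, pixels_per_class = 1500L,
                 rbc_range = c(0.15, 0.80), wbc_fraction = 0.05))
  .mergeDefaults(config, defaults)
}

# Evenly spaced test compositions spanning the configured RBC range.
.testFractionGrid <- function(n, rbcRange, wbc) {
  rbc <- seq(rbcRange[2], rbcRange[1], length.out = n)
  lapply(rbc, function(r) c(rbc = r, wbc = wbc, fibrin = 1 - r - wbc))
}

#' Run the quantification pipeline
#'
#' Executes the requested stages in the standard operating order on
#' synthetic data: generate annotated training/validation sets and held-out
#' test slides, train the exclusion and classification models, combine them,
#' batch-quantify the test set, run the color-threshold comparator on the
#' same slides, and compute the agreement report (with synthetic clinical
#' mean-HU values generated from the true RBC fraction, see the vignette).
#' Partial runs are supported: with `stages = "quantify"` and a
#' `model_path`, a saved Main model is applied to the images in
#' `images_dir`.
#'
#' @param config configuration list or JSON path, see [pipelineConfig].
#' @return list with the completed `config`, file `paths`, and (depending on
#'   stages) `models`, `mlTable`, `thresholdTable`, `report`, `manifest`.
#' @export
runPipeline <- function(config = list()) {
  cfg <- pipelineConfig(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logOn <- isTRUE(cfg$log)
  stages <- cfg$stages
  paths <- list(out_dir = cfg$out_dir)
  out <- list(config = cfg, paths = paths)
  fconf <- featureConfig(cfg$feature$window_radius)
  gamma <- if (is.null(cfg$svm$gamma) || is.na(cfg$svm$gamma)) 1 / 18
           else cfg$svm$gamma

  trainSet <- valSet <- NULL
  testSlides <- list()
  if ("synth" %in% stages) {
    .log(logOn, "synth: seed %d, %dx%d px, %d train / %d val / %d test",
         cfg$seed, cfg$synth$height, cfg$synth$width, cfg$synth$n_train,
         cfg$synth$n_val, cfg$synth$n_test)
    baseParams <- function(seed, fractions = c(rbc = 0.45, wbc = 0.1,
                                               fibrin = 0.45), folds) {
      synthParams(height = cfg$synth$height, width = cfg$synth$width,
                  targetFractions = fractions,
                  backgroundFraction = cfg$synth$background_fraction,
                  nArtefactFolds = folds, noiseSd = cfg$synth$noise_sd,
                  seed = seed)
    }
    trainSet <- generateAnnotatedSet(
      baseParams(cfg$seed, folds = cfg$synth$n_folds),
      nImages = cfg$synth$n_train,
      pixelsPerClass = cfg$synth$pixels_per_class)
    valSet <- generateAnnotatedSet(
      baseParams(cfg$seed + 100L, folds = cfg$synth$n_folds),
      nImages = cfg$synth$n_val,
      pixelsPerClass = cfg$synth$pixels_per_class)
    grid <- .testFractionGrid(cfg$synth$n_test, cfg$synth$rbc_range,
                              cfg$synth$wbc_fraction)
    testSlides <- lapply(seq_along(grid), function(i)
      generateClotSlide(baseParams(cfg$seed + 200L + i, grid[[i]],
                                   folds = 0L),
                        id = sprintf("test-%02d", i)))
    # persist images, annotations and a manifest
    synthDir <- file.path(cfg$out_dir, "synth")
    dir.create(synthDir, showWarnings = FALSE)
    regions <- list()
    for (s in c(trainSet, valSet)) {
      writeImage(s$image, file.path(synthDir, paste0(s$image@id, ".png")))
      regions <- c(regions, s$regions)
    }
    writeAnnotations(regions, file.path(synthDir, "annotations.tsv"))
    for (s in testSlides)
      writeImage(s$image, file.path(synthDir, paste0(s$image@id, ".png")))
    manifest <- data.frame(
      image_id = vapply(testSlides, function(s) s$image@id, ""),
      true_rbc = 100 * vapply(testSlides, function(s) s$fractions["rbc"], 0),
      true_wbc = 100 * vapply(testSlides, function(s) s$fractions["wbc"], 0),
      true_fibrin = 100 * vapply(testSlides,
                                 function(s) s$fractions["fibrin"], 0))
    utils::write.csv(manifest, file.path(synthDir, "manifest.csv"),
                     row.names = FALSE)
    out$manifest <- manifest
    paths$synth <- synthDir
  }

  main <- NULL
  if ("train" %in% stages) {
    if (is.null(trainSet))
      stop("stage 'train' requires stage 'synth' (or use model_path with ",
           "a quantify-only run)")
    imgs <- lapply(trainSet, `[[`, "image")
    regs <- do.call(c, lapply(trainSet, `[[`, "regions"))
    .log(logOn, "train: exclusion model (per_class %d)", cfg$per_class)
    exSamp <- sampleTrainingPixels(imgs, relabelRegions(regs),
                                   perClass = cfg$per_class,
                                   seed = cfg$seed, config = fconf)
    exclusion <- trainPixelModel(exSamp$x, exSamp$y, EXCLUSION_LABELS,
                                 config = fconf, cost = cfg$svm$cost,
                                 gamma = gamma, seed = cfg$seed,
                                 meta = list(images = vapply(imgs, imageId,
                                                             "")))
    .log(logOn, "train: classification model")
    tisRegs <- Filter(function(r) r@label %in% TISSUE_LABELS, regs)
    clSamp <- sampleTrainingPixels(imgs, tisRegs, perClass = cfg$per_class,
                                   seed = cfg$seed, config = fconf)
    classification <- trainPixelModel(clSamp$x, clSamp$y, TISSUE_LABELS,
                                      config = fconf, cost = cfg$svm$cost,
                                      gamma = gamma, seed = cfg$seed,
                                      meta = list(images = vapply(imgs,
                                                                  imageId,
                                                                  "")))
    # validation accuracy on the held-out annotated pixels
    if (!is.null(valSet)) {
      vim <- lapply(valSet, `[[`, "image")
      vre <- do.call(c, lapply(valSet, `[[`, "regions"))
      va <- sampleTrainingPixels(vim, relabelRegions(vre), perClass = 500L,
                                 seed = cfg$seed + 1L, config = fconf)
      pred <- EXCLUSION_LABELS[.svmPredictIndex(exclusion,
                                                .standardize(exclusion,
                                                             va$x))]
      .log(logOn, "validate: exclusion pixel accuracy %.3f",
           mean(pred == va$y))
      vc <- sampleTrainingPixels(vim,
                                 Filter(function(r)
                                   r@label %in% TISSUE_LABELS, vre),
                                 perClass = 500L, seed = cfg$seed + 2L,
                                 config = fconf)
      predc <- TISSUE_LABELS[.svmPredictIndex(classification,
                                              .standardize(classification,
                                                           vc$x))]
      .log(logOn, "validate: classification pixel accuracy %.3f",
           mean(predc == vc$y))
    }
    out$models <- list(exclusion = exclusion,
                       classification = classification)
  }

  if ("combine" %in% stages) {
    if (!is.null(out$models)) {
      main <- combineModels(out$models$exclusion, out$models$classification)
    } else if (!is.null(cfg$model_path)) {
      main <- loadModel(cfg$model_path)
    } else stop("stage 'combine' requires trained models or a model_path")
    paths$model <- file.path(cfg$out_dir, "main.model")
    saveModel(main, paths$model)
    .log(logOn, "combine: main model written to %s", paths$model)
    out$models$main <- main
  }

  if ("quantify" %in% stages) {
    if (is.null(main)) {
      if (is.null(cfg$model_path))
        stop("stage 'quantify' requires a combined model: run 'combine' or ",
             "set model_path")
      main <- loadModel(cfg$model_path)
    }
    images <- if (length(testSlides)) lapply(testSlides, `[[`, "image")
      else {
        if (is.null(cfg$images_dir))
          stop("stage 'quantify' without synth requires images_dir")
        files <- sort(list.files(cfg$images_dir,
                                 pattern = "\\.(png|tif|tiff)$",
                                 full.names = TRUE))
        lapply(files, readImage)
      }
    .log(logOn, "quantify: %d slides (stride %d)", length(images),
         cfg$stride)
    ml <- batchQuantify(main, images, stride = cfg$stride)
    paths$results <- file.path(cfg$out_dir, "results.csv")
    utils::write.csv(ml, paths$results, row.names = FALSE)
    out$mlTable <- ml
  }

  if ("threshold" %in% stages) {
    if (!length(testSlides))
      stop("stage 'threshold' requires stage 'synth' in this run")
    .log(logOn, "threshold: comparator on %d slides (tolerance %g)",
         length(testSlides), cfg$tolerance)
    images <- lapply(testSlides, `[[`, "image")
    regionSets <- lapply(seq_along(testSlides), function(i) {
      s <- testSlides[[i]]
      .withSeed(cfg$seed + 500L + i,
                do.call(c, lapply(match(TISSUE_LABELS, ALL_LABELS),
                                  function(code)
          .sampleClassRegions(s$truth, code, 400L, s$image@id)$regions)))
    })
    thr <- thresholdQuantifyBatch(images, regionSets,
                                  tolerance = cfg$tolerance,
                                  denominator = cfg$denominator)
    paths$threshold <- file.path(cfg$out_dir, "threshold.csv")
    utils::write.csv(thr, paths$threshold, row.names = FALSE)
    out$thresholdTable <- thr
  }

  if ("stats" %in% stages) {
    if (is.null(out$mlTable) || is.null(out$thresholdTable))
      stop("stage 'stats' requires the quantify and threshold stages")
    a <- out$mlTable; b <- out$thresholdTable
    names(a)[names(a) == "image_id"] <- "clot_id"
    names(b)[names(b) == "image_id"] <- "clot_id"
    # synthetic clinical attenuation: RBC-rich clots tend hyperdense
    clinical <- .withSeed(cfg$seed + 900L, data.frame(
      clot_id = a$clot_id,
      mean_hu = 38 + 0.28 * out$manifest$true_rbc +
        stats::rnorm(nrow(a), 0, 4)))
    report <- agreementReport(a, b, clinical)
    paths$report <- file.path(cfg$out_dir, "report.json")
    reportAsList(report, paths$report)
    paths$clinical <- file.path(cfg$out_dir, "clinical.csv")
    utils::write.csv(clinical, paths$clinical, row.names = FALSE)
    .log(logOn, "stats: pooled rho %.3f, bias %.3f", report@pooledSpearman@rho,
         report@pooledBlandAltman@bias)
    out$report <- report
  }

  out$paths <- paths
  out
}
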