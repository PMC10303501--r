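## Pipeline: one flat config with per-stage sections drives
## synth -> segment -> split/augment -> (train) -> extract x2 organs ->
## fuse -> classify -> evaluate -> analyze, writing a versioned run
## directory with a config snapshot, manifests, metrics and figures.

#' Default pipeline configuration
#'
#' A complete configuration list with one block per stage. [pipelineConfig()]
#' merges user settings over these defaults and rejects unknown keys.
#'
#' @return Named list of stage blocks.
#' @export
defaultPipelineConfig <- function() {
  list(
    runName = "run",
    outputRoot = tempfile("psf_run_"),
    seed = 1L,
    synthetic = list(enabled = TRUE, K = 6L, perClassScans = 3L,
                     objectsPerScan = 8L, nSiblingPairs = 0L,
                     complementarity = 0, siblingDelta = 0.015,
                     canvas = c(600L, 600L)),
    input = list(podScans = NULL, seedScans = NULL),
    segmentation = list(minAreaPx = 64L, connectivity = 8L,
                        dropBorderTouching = FALSE, method = "otsu",
                        threshold = NULL, canvasSize = 300L,
                        overflow = "error"),
    augmentation = list(enabled = FALSE, targetPerGroup = 1000L,
                        mode = "split_before_augment",
                        ops = c("rotate", "shift", "flip_vertical",
                                "mirror_horizontal"),
                        rotateAngles = c(90, 180, 270),
                        shiftMaxFraction = 0.1),
    split = list(ratios = c(8, 1, 1)),
    train = list(enabled = FALSE, maxEpochs = 2L, batchSize = 32L,
                 learningRate = 3e-4, validationFrequency = 64L,
                 freezePolicy = "freeze_all_conv"),
    features = list(backbone = "tiny", layer = NULL),
    fusion = list(strategy = "round_robin", kernel = "linear", cost = 1,
                  pairsPerClass = NULL),
    evaluate = list(singleOrgan = TRUE),
    analyze = list(enabled = TRUE,
                   tsne = list(enabled = FALSE, dims = 2L, perplexity = 12),
                   clusterTree = list(enabled = TRUE, via3d = FALSE,
                                      linkage = "ward.D2"),
                   gradCam = list(enabled = FALSE, layer = "relu3", n = 2L)))
}

mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s)%s: %s",
          if (nzchar(path)) paste0(" under '", path, "'") else "",
          paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]]))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]],
                                    paste0(path, nm, "."))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Build (and validate) a pipeline configuration
#'
#' @param x A named list of overrides, a YAML file path, or `NULL` for the
#'   defaults.
#' @param ... Further overrides applied on top (e.g. `seed = 7`).
#' @return Validated configuration list.
#' @export
pipelineConfig <- function(x = NULL, ...) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  cfg <- mergeConfig(defaultPipelineConfig(), x)
  cfg <- mergeConfig(cfg, list(...))
  cfg
}

#' Demo configuration: small synthetic end-to-end run
#'
#' @param seed RNG seed.
#' @param outputRoot Run directory root.
#' @return Configuration list for a complete but small pipeline run.
#' @export
demoConfig <- function(seed = 1L, outputRoot = tempfile("psf_demo_")) {
  pipelineConfig(list(
    runName = "demo", outputRoot = outputRoot, seed = as.integer(seed),
    synthetic = list(K = 6L, perClassScans = 3L, objectsPerScan = 8L,
                     complementarity = 0.5)))
}

stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

logStage <- function(log, stage, seed, fmt, ...) {
  line <- sprintf("[%s] (seed %s) %s", stage, as.character(seed),
                  sprintf(fmt, ...))
  cat(line, "\n", sep = "", file = log, append = TRUE)
  message(line)
}

#' Run the full dual-branch fusion pipeline
#'
#' Executes segmentation, split (and optional augmentation), optional
#' backbone fine-tuning, per-organ feature extraction, pod-seed pairing and
#' fusion, SVM training, evaluation and analysis, from either synthetic
#' scans (default) or directories of real scan images. All randomness
#' derives from `config$seed`; rerunning with the same config reproduces
#' the run.
#'
#' @param config A configuration from [pipelineConfig()].
#' @return Invisible report list: run directory, manifests, metrics
#'   (fused/single-organ accuracies, macro metrics), confusion matrix and
#'   file paths.
#' @export
runPipeline <- function(config = demoConfig()) {
  cfg <- pipelineConfig(config)
  runDir <- file.path(cfg$outputRoot, cfg$runName)
  for (d in c("", "objects", "metrics", "figures"))
    dir.create(file.path(runDir, d), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(runDir, "config.yaml"))
  log <- file.path(runDir, "run.log")
  cat("", file = log)

  # ---- data --------------------------------------------------------------
  if (isTRUE(cfg$synthetic$enabled)) {
    syn <- stageError("synth", generateDataset(
      K = cfg$synthetic$K, perClassScans = cfg$synthetic$perClassScans,
      objectsPerScan = cfg$synthetic$objectsPerScan, outDir = runDir,
      seed = childSeed(cfg$seed, 1L),
      nSiblingPairs = cfg$synthetic$nSiblingPairs,
      complementarity = cfg$synthetic$complementarity,
      siblingDelta = cfg$synthetic$siblingDelta,
      canvas = cfg$synthetic$canvas))
    scanManifest <- syn$scanManifest
    logStage(log, "synth", cfg$seed, "%d scans, %d classes",
             nrow(scanManifest), cfg$synthetic$K)
  } else {
    syn <- NULL
    scanManifest <- stageError("input", {
      listScans <- function(dir, org) {
        if (is.null(dir)) stopf("no %s scan directory configured", org)
        files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                                 full.names = TRUE))
        if (!length(files)) stopf("no %s scans found in %s", org, dir)
        data.frame(path = files,
                   class = sub("_.*$", "", basename(files)),
                   organ = org,
                   scan_id = tools::file_path_sans_ext(basename(files)),
                   stringsAsFactors = FALSE)
      }
      rbind(listScans(cfg$input$podScans, "pod"),
            listScans(cfg$input$seedScans, "seed"))
    })
  }

  # ---- segmentation ------------------------------------------------------
  manifest <- stageError("segment", {
    parts <- lapply(seq_len(nrow(scanManifest)), function(i) {
      row <- scanManifest[i, ]
      scan <- if (!is.null(syn) && !is.null(syn$scans))
        syn$scans[[row$scan_id]]
      else ScanImage(readImageFile(row$path), organ = row$organ,
                     classLabel = row$class, scanId = row$scan_id)
      segmentScan(scan, minAreaPx = cfg$segmentation$minAreaPx,
                  connectivity = cfg$segmentation$connectivity,
                  dropBorderTouching = cfg$segmentation$dropBorderTouching,
                  method = cfg$segmentation$method,
                  threshold = cfg$segmentation$threshold,
                  canvasSize = cfg$segmentation$canvasSize,
                  overflow = cfg$segmentation$overflow,
                  outDir = file.path(runDir, "objects"))$manifest
    })
    do.call(rbind, parts)
  })
  logStage(log, "segment", cfg$seed, "%d objects from %d scans",
           nrow(manifest), nrow(scanManifest))

  # ---- split / augmentation ---------------------------------------------
  manifest <- stageError("split", {
    if (isTRUE(cfg$augmentation$enabled)) {
      policy <- augmentationPolicy(
        ops = cfg$augmentation$ops,
        rotateAngles = cfg$augmentation$rotateAngles,
        shiftMaxFraction = cfg$augmentation$shiftMaxFraction,
        seed = childSeed(cfg$seed, 2L))
      augmentManifest(manifest, cfg$augmentation$targetPerGroup, policy,
                      mode = cfg$augmentation$mode,
                      ratios = cfg$split$ratios,
                      seed = childSeed(cfg$seed, 3L))
    } else {
      splitManifest(manifest, ratios = cfg$split$ratios,
                    seed = childSeed(cfg$seed, 3L))
    }
  })
  writeManifest(manifest, file.path(runDir, "manifest.csv"))
  logStage(log, "split", childSeed(cfg$seed, 3L), "%s",
           paste(names(table(manifest$split)), table(manifest$split),
                 collapse = " ", sep = "="))

  # ---- backbones (two identical branches) --------------------------------
  classes <- sort(unique(manifest$class))
  branches <- stageError("train", {
    base <- buildBackbone(cfg$features$backbone,
                          numClasses = length(classes),
                          seed = childSeed(cfg$seed, 4L))
    out <- list(pod = base, seed = base)
    if (isTRUE(cfg$train$enabled)) {
      tc <- trainConfig(batchSize = cfg$train$batchSize,
                        learningRate = cfg$train$learningRate,
                        validationFrequency = cfg$train$validationFrequency,
                        maxEpochs = cfg$train$maxEpochs,
                        freezePolicy = cfg$train$freezePolicy,
                        seed = childSeed(cfg$seed, 5L))
      for (org in c("pod", "seed")) {
        m <- manifest[manifest$organ == org, ]
        ft <- finetuneBackbone(base, m[m$split == "train", ],
                               m[m$split == "val", ], tc)
        out[[org]] <- ft$model
        logStage(log, "train", tc@seed, "%s branch final val acc %.3f", org,
                 tail(ft$history$valAccuracy, 1L))
      }
    }
    out
  })

  # ---- feature extraction ------------------------------------------------
  layer <- if (is.null(cfg$features$layer))
    branches$pod@spec@headFeatureLayer else cfg$features$layer
  feats <- stageError("extract", {
    lapply(c(pod = "pod", seed = "seed"), function(org) {
      m <- manifest[manifest$organ == org, ]
      if (nrow(m) == 0L) stopf("no %s data after segmentation", org)
      extractFeatures(branches[[org]], layer, m)
    })
  })
  logStage(log, "extract", cfg$seed, "layer %s: %d pod + %d seed rows",
           layer, ncol(feats$pod), ncol(feats$seed))

  # ---- pairing / fusion / classification ---------------------------------
  podM <- manifest[manifest$organ == "pod", ]
  seedM <- manifest[manifest$organ == "seed", ]
  fused <- stageError("fuse", {
    lapply(c(train = "train", val = "val", test = "test"), function(sp) {
      pm <- makePairs(podM, seedM, split = sp,
                      strategy = cfg$fusion$strategy,
                      pairsPerClass = cfg$fusion$pairsPerClass,
                      seed = childSeed(cfg$seed, 6L))
      fuseFeatures(feats$pod, feats$seed, pm)
    })
  })
  clf <- stageError("classify", trainFusionClassifier(
    fused$train, kernel = cfg$fusion$kernel, cost = cfg$fusion$cost))

  # ---- evaluation --------------------------------------------------------
  report <- stageError("evaluate", {
    predTest <- predict(clf, fused$test)
    cm <- confusionMatrix(fused$test@labels, predTest, classes)
    metrics <- suppressWarnings(precisionRecallF1(cm))
    valAcc <- mean(predict(clf, fused$val) == fused$val@labels)
    res <- list(cm = cm, metrics = metrics,
                fusedTestAccuracy = accuracy(cm),
                fusedValAccuracy = valAcc)
    if (isTRUE(cfg$evaluate$singleOrgan)) {
      for (org in c("pod", "seed")) {
        sel <- if (org == "pod") seq_len(fused$train@podDim)
               else fused$train@podDim + seq_len(fused$train@seedDim)
        sClf <- trainFusionClassifier(fused$train@values[, sel, drop = FALSE],
                                      kernel = cfg$fusion$kernel,
                                      cost = cfg$fusion$cost,
                                      labels = fused$train@labels)
        sPred <- predict(sClf, fused$test@values[, sel, drop = FALSE])
        res[[paste0(org, "TestAccuracy")]] <- mean(sPred == fused$test@labels)
        res[[paste0(org, "Confusion")]] <-
          confusionMatrix(fused$test@labels, sPred, classes)
      }
    }
    res
  })
  writeMetrics(report$metrics, cm = report$cm,
               jsonPath = file.path(runDir, "metrics", "metrics.json"),
               csvPath = file.path(runDir, "metrics", "per_class.csv"))
  writeConfusionHeatmap(report$cm,
                        file.path(runDir, "figures", "confusion.png"))
  logStage(log, "evaluate", cfg$seed, "fused test acc %.3f",
           report$fusedTestAccuracy)

  # ---- analysis ----------------------------------------------------------
  analysis <- list()
  if (isTRUE(cfg$analyze$enabled)) {
    analysis <- stageError("analyze", {
      out <- list()
      cent <- classCentroids(fused$train)
      if (isTRUE(cfg$analyze$clusterTree$enabled)) {
        tree <- buildClusterTree(cent, via3d = cfg$analyze$clusterTree$via3d,
                                 linkage = cfg$analyze$clusterTree$linkage,
                                 seed = childSeed(cfg$seed, 7L))
        writeNewick(tree, file.path(runDir, "figures", "cluster_tree.nwk"))
        out$clusterTree <- tree
      }
      if (isTRUE(cfg$analyze$tsne$enabled)) {
        emb <- tsneEmbed(fused$test@values, dims = cfg$analyze$tsne$dims,
                         perplexity = cfg$analyze$tsne$perplexity,
                         seed = childSeed(cfg$seed, 8L))
        df <- data.frame(coords(emb), class = fused$test@labels)
        write.csv(df, file.path(runDir, "figures", "tsne.csv"),
                  row.names = FALSE)
        out$tsne <- emb
      }
      if (isTRUE(cfg$analyze$gradCam$enabled)) {
        tm <- manifest[manifest$split == "test", ]
        tm <- head(tm, cfg$analyze$gradCam$n)
        for (i in seq_len(nrow(tm))) {
          g <- gradCam(branches[[tm$organ[i]]],
                       readImageFile(tm$path[i]),
                       layer = cfg$analyze$gradCam$layer,
                       targetClass = match(tm$class[i], classes))
          writeImageFile(g@overlay, file.path(
            runDir, "figures",
            sprintf("gradcam_%02d_%s.png", i, tm$class[i])))
        }
        out$gradCamN <- nrow(tm)
      }
      out
    })
  }

  invisible(list(runDir = runDir, config = cfg, manifest = manifest,
                 classes = classes, layer = layer,
                 fused = fused, classifier = clf,
                 confusion = report$cm, metrics = report$metrics,
                 fusedTestAccuracy = report$fusedTestAccuracy,
                 fusedValAccuracy = report$fusedValAccuracy,
                 podTestAccuracy = report$podTestAccuracy,
                 seedTestAccuracy = report$seedTestAccuracy,
                 analysis = analysis))
}
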