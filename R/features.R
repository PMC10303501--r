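## Feature extraction and fine-tuning.

#' Per-channel input normalization constants
#'
#' `defaultNormalization()` is the identity (mean 0, sd 1): it preserves the
#' black-canvas contract (background pixels stay exactly 0 through the
#' network input), which keeps activations of randomly initialized or
#' from-scratch fine-tuned backbones localized on the object. When loading
#' ImageNet-pretrained weights, use `imagenetNormalization()` (the standard
#' ImageNet channel statistics) instead. Both are accepted by
#' [extractFeatures()], [finetuneBackbone()] and [gradCam()].
#' @return List with `mean` and `sd`, each length 3.
#' @export
defaultNormalization <- function()
  list(mean = c(0, 0, 0), sd = c(1, 1, 1))

#' @rdname defaultNormalization
#' @export
imagenetNormalization <- function()
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))

# Resize (bilinear) to the backbone input size and normalize channels.
preprocessImage <- function(px, spec, norm = defaultNormalization()) {
  d <- inputSize(spec)
  if (!identical(dim(px)[1:2], d[1:2])) px <- resizeBilinear(px, d[1L], d[2L])
  for (ch in 1:3) px[, , ch] <- (px[, , ch] - norm$mean[ch]) / norm$sd[ch]
  px
}

# Accepts a list of NormalizedObjectImage / arrays, or a manifest data.frame
# with a path column. Returns list(pixels = list of arrays, ids, labels).
resolveImages <- function(images) {
  if (is.data.frame(images)) {
    px <- lapply(images$path, readImageFile)
    return(list(pixels = px, ids = images$path,
                labels = if ("class" %in% names(images))
                  as.character(images$class) else NULL))
  }
  if (!is.list(images)) stopf("images must be a list or a manifest data.frame")
  px <- lapply(images, function(im)
    if (is(im, "NormalizedObjectImage")) pixels(im) else im)
  labels <- vapply(images, function(im)
    if (is(im, "NormalizedObjectImage")) classLabel(im) else NA_character_,
    character(1L))
  ids <- if (!is.null(names(images))) names(images)
         else sprintf("img%05d", seq_along(images))
  list(pixels = px, ids = ids,
       labels = if (all(is.na(labels))) NULL else labels)
}

#' Extract deep features at a named layer
#'
#' Runs each image through the backbone and exports the activation of
#' `layer`, flattened row-major, as one row of a [FeatureSet-class]. Rows
#' are in input (manifest) order.
#'
#' @param model A [CnnModel-class].
#' @param layer One of the model's declared feature layers (see
#'   [featureLayers()]); defaults to the global-pooling fusion layer.
#' @param images List of [NormalizedObjectImage-class]/arrays, or a manifest
#'   data.frame with a `path` column.
#' @param norm Channel normalization (see [defaultNormalization()]).
#' @return A [FeatureSet-class] (`n x d`, `d` per the backbone spec).
#' @export
extractFeatures <- function(model, layer = model@spec@headFeatureLayer,
                            images, norm = defaultNormalization()) {
  stopifnot(is(model, "CnnModel"))
  fl <- featureLayers(model)
  if (!layer %in% names(fl))
    stopf("unknown feature layer '%s'; declared: %s", layer,
          paste(names(fl), collapse = ", "))
  resolved <- resolveImages(images)
  n <- length(resolved$pixels)
  if (n == 0L) stopf("extractFeatures: no images")
  d <- fl[[layer]]
  out <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    x <- preprocessImage(resolved$pixels[[i]], model@spec, norm)
    cache <- nnForward(model, x, upto = layer)
    v <- flattenRowMajor(getActivation(cache, layer))
    if (length(v) != d)
      stopf("layer '%s' produced %d values, spec declares %d", layer,
            length(v), d)
    out[i, ] <- v
  }
  if (!all(is.finite(out))) stopf("non-finite features extracted")
  cd <- if (is.null(resolved$labels)) NULL
        else data.frame(class = resolved$labels)
  FeatureSet(out, rowIds = resolved$ids, layerName = layer,
             backboneName = model@spec@name, colData = cd)
}

#' Predict class probabilities with the network head
#'
#' @param model A [CnnModel-class].
#' @param images As in [extractFeatures()].
#' @param classLevels Optional class labels for the columns.
#' @return `n x numClasses` matrix of softmax probabilities.
#' @export
predictProb <- function(model, images, classLevels = NULL) {
  probLayer <- names(featureLayers(model))[
    featureLayers(model) == numClasses(model)]
  probLayer <- probLayer[length(probLayer)]
  fs <- extractFeatures(model, probLayer, images)
  p <- featureMatrix(fs)
  if (!is.null(classLevels)) colnames(p) <- classLevels
  p
}

#' Fine-tune a backbone
#'
#' Seeded mini-batch SGD (momentum 0.9) with the classical transfer-learning
#' recipe. With `freezePolicy = "freeze_all_conv"` (default) all layers
#' below the head are frozen: features at the head layer are extracted once
#' and only the classification head is retrained, which is fast and exactly
#' preserves every convolution parameter. With `"none"` the full network is
#' trained by backpropagation. Training/validation metrics are recorded
#' every `validationFrequency` steps and at the end of training.
#'
#' @param model A [CnnModel-class].
#' @param train,val Lists of [NormalizedObjectImage-class] (labelled), or
#'   manifest data.frames with `path` and `class` columns.
#' @param config A [TrainConfig-class].
#' @param norm Channel normalization.
#' @return List with `model` (updated [CnnModel-class]), `history`
#'   (data.frame: step, epoch, trainLoss, valAccuracy) and `classLevels`.
#' @export
finetuneBackbone <- function(model, train, val, config = trainConfig(),
                             norm = defaultNormalization()) {
  stopifnot(is(model, "CnnModel"), is(config, "TrainConfig"))
  trainSet <- resolveImages(train)
  valSet <- resolveImages(val)
  if (length(trainSet$pixels) == 0L || length(valSet$pixels) == 0L)
    stopf("finetuneBackbone: empty split")
  if (is.null(trainSet$labels)) stopf("training images must carry labels")
  classLevels <- sort(unique(trainSet$labels))
  if (length(classLevels) != numClasses(model))
    stopf("%d classes in training data but head has %d outputs",
          length(classLevels), numClasses(model))
  yTrain <- match(trainSet$labels, classLevels)
  yVal <- match(valSet$labels, classLevels)
  if (config@freezePolicy == "freeze_all_conv")
    finetuneHead(model, trainSet, yTrain, valSet, yVal, config, norm,
                 classLevels)
  else
    finetuneFull(model, trainSet, yTrain, valSet, yVal, config, norm,
                 classLevels)
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

finetuneHead <- function(model, trainSet, yTrain, valSet, yVal, config, norm,
                         classLevels) {
  headLayer <- model@spec@headFeatureLayer
  Xtr <- featureMatrix(extractFeatures(model, headLayer, trainSet$pixels,
                                       norm))
  Xva <- featureMatrix(extractFeatures(model, headLayer, valSet$pixels, norm))
  headName <- headNodeName(model)
  node <- graphNode(model@graph, headName)
  W <- node$W; b <- node$b
  K <- length(b)
  n <- nrow(Xtr)
  vW <- W * 0; vb <- b * 0
  mom <- 0.9
  hist <- list()
  step <- 0L
  withSeed(config@seed, {
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config@batchSize)) {
        idx <- ord[start:min(start + config@batchSize - 1L, n)]
        Xb <- Xtr[idx, , drop = FALSE]
        P <- softmaxRows(Xb %*% W + matrix(b, length(idx), K, byrow = TRUE))
        Y <- matrix(0, length(idx), K)
        Y[cbind(seq_along(idx), yTrain[idx])] <- 1
        loss <- -mean(log(pmax(P[cbind(seq_along(idx), yTrain[idx])], 1e-12)))
        G <- (P - Y) / length(idx)
        vW <- mom * vW - config@learningRate * crossprod(Xb, G)
        vb <- mom * vb - config@learningRate * colSums(G)
        W <- W + vW; b <- b + vb
        step <- step + 1L
        if (step %% config@validationFrequency == 0L) {
          hist[[length(hist) + 1L]] <- data.frame(
            step = step, epoch = epoch, trainLoss = loss,
            valAccuracy = headAccuracy(Xva, W, b, yVal))
        }
      }
    }
  })
  hist[[length(hist) + 1L]] <- data.frame(
    step = step, epoch = config@maxEpochs, trainLoss = NA_real_,
    valAccuracy = headAccuracy(Xva, W, b, yVal))
  model@graph <- graphSetParams(model@graph, headName, list(W = W, b = b))
  list(model = model, history = do.call(rbind, hist),
       classLevels = classLevels)
}

headAccuracy <- function(X, W, b, y) {
  pred <- max.col(X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE),
                  ties.method = "first")
  mean(pred == y)
}

graphSetParams <- function(graph, name, params) {
  for (i in seq_along(graph)) {
    if (graph[[i]]$name == name) {
      for (p in names(params)) graph[[i]][[p]] <- params[[p]]
      return(graph)
    }
  }
  stopf("no node named '%s'", name)
}

finetuneFull <- function(model, trainSet, yTrain, valSet, yVal, config, norm,
                         classLevels) {
  graph <- model@graph
  probName <- graph[[length(graph)]]$name
  K <- numClasses(model)
  n <- length(trainSet$pixels)
  xs <- lapply(trainSet$pixels, preprocessImage, spec = model@spec,
               norm = norm)
  vel <- list()
  mom <- 0.9
  hist <- list()
  step <- 0L
  valAcc <- function(g) {
    m2 <- model; m2@graph <- g
    p <- predictProb(m2, valSet$pixels)
    mean(max.col(p, ties.method = "first") == yVal)
  }
  withSeed(config@seed, {
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config@batchSize)) {
        idx <- ord[start:min(start + config@batchSize - 1L, n)]
        acc <- list()
        loss <- 0
        for (i in idx) {
          cache <- nnForward(graph, xs[[i]])
          p <- cache$acts[[probName]]
          loss <- loss - log(max(p[yTrain[i]], 1e-12))
          seed <- numeric(K)
          seed[yTrain[i]] <- -1 / max(p[yTrain[i]], 1e-12)
          bp <- nnBackward(graph, cache, setNames(list(seed), probName),
                           needParams = TRUE)
          for (nm in names(bp$dParams)) {
            if (is.null(acc[[nm]])) acc[[nm]] <- bp$dParams[[nm]]
            else for (pp in names(acc[[nm]]))
              acc[[nm]][[pp]] <- acc[[nm]][[pp]] + bp$dParams[[nm]][[pp]]
          }
        }
        deltas <- list()
        for (nm in names(acc)) {
          if (is.null(vel[[nm]]))
            vel[[nm]] <- lapply(acc[[nm]], function(a) a * 0)
          for (pp in names(acc[[nm]])) {
            vel[[nm]][[pp]] <- mom * vel[[nm]][[pp]] -
              config@learningRate * acc[[nm]][[pp]] / length(idx)
          }
          deltas[[nm]] <- vel[[nm]]
        }
        graph <- graphApplyDeltas(graph, deltas)
        step <- step + 1L
        if (step %% config@validationFrequency == 0L)
          hist[[length(hist) + 1L]] <- data.frame(
            step = step, epoch = epoch, trainLoss = loss / length(idx),
            valAccuracy = valAcc(graph))
      }
    }
  })
  hist[[length(hist) + 1L]] <- data.frame(
    step = step, epoch = config@maxEpochs, trainLoss = NA_real_,
    valAccuracy = valAcc(graph))
  model@graph <- graph
  list(model = model, history = do.call(rbind, hist),
       classLevels = classLevels)
}
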