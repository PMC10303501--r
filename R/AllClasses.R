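#' @include AllGenerics.R
NULL

## Central S4 data containers.
##
## Image pixel data are stored as numeric arrays dim (H, W, 3) with values in
## [0, 1] (the native convention of R's png/tiff readers; the source scans are
## 8-bit, so 1.0 corresponds to the 8-bit value 255). Background black is
## exactly 0. Bounding boxes are 0-based and half-open on their max edges:
## (rowMin, colMin, rowMax, colMax) spans rows rowMin..rowMax-1.

#' ScanImage: a raw multi-object scanner image
#'
#' An RGB raster containing several seeds or pods of a single class on a
#' (near-)black background, plus its organ, class label and scan identifier.
#'
#' @slot pixels Numeric array `H x W x 3`, values in `[0, 1]`.
#' @slot organ `"pod"` or `"seed"`.
#' @slot classLabel Class (line) label.
#' @slot scanId Unique scan identifier.
#' @export
setClass("ScanImage", representation(
  pixels = "array", organ = "character",
  classLabel = "character", scanId = "character"))

setValidity("ScanImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3L] != 3L)
    return("pixels must be an H x W x 3 array")
  if (dim(p)[1L] < 1L || dim(p)[2L] < 1L) return("image must be at least 1 x 1")
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    return("pixel values must lie in [0, 1]")
  if (!object@organ %in% c("pod", "seed"))
    return("organ must be 'pod' or 'seed'")
  TRUE
})

#' Construct a ScanImage
#'
#' @param pixels Numeric array `H x W x 3` in `[0, 1]`.
#' @param organ `"pod"` or `"seed"`.
#' @param classLabel,scanId Identifiers.
#' @return A [ScanImage-class] object.
#' @export
ScanImage <- function(pixels, organ, classLabel = "unknown", scanId = "scan") {
  new("ScanImage", pixels = pixels, organ = organ,
      classLabel = as.character(classLabel), scanId = as.character(scanId))
}

#' BinaryMask: foreground/background segmentation mask
#'
#' @slot mask Logical matrix, `TRUE` = object foreground.
#' @export
setClass("BinaryMask", representation(mask = "matrix"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (anyNA(object@mask)) return("mask must not contain NA")
  TRUE
})

#' ObjectROI: one connected object's bounding box and mask crop
#'
#' @slot bbox Integer `(rowMin, colMin, rowMax, colMax)`, 0-based, half-open
#'   on the max edges.
#' @slot areaPx Foreground pixel count.
#' @slot maskCrop Logical matrix of the mask restricted to `bbox`.
#' @export
setClass("ObjectROI", representation(
  bbox = "integer", areaPx = "integer", maskCrop = "matrix"))

setValidity("ObjectROI", function(object) {
  b <- object@bbox
  if (length(b) != 4L) return("bbox must have 4 entries")
  if (b[3L] <= b[1L] || b[4L] <= b[2L]) return("bbox must be non-empty")
  if (object@areaPx <= 0L) return("areaPx must be positive")
  if (!identical(dim(object@maskCrop),
                 c(b[3L] - b[1L], b[4L] - b[2L])))
    return("maskCrop dimensions must match bbox extent")
  if (sum(object@maskCrop) != object@areaPx)
    return("areaPx must equal the number of TRUE pixels in maskCrop")
  TRUE
})

#' NormalizedObjectImage: a single object on a square black canvas
#'
#' A segmented object pasted centred onto a `canvasSize x canvasSize` black
#' canvas; every pixel outside the pasted mask is exactly (0,0,0), so true
#' object size is preserved while meeting a CNN input-size contract.
#'
#' @slot pixels Numeric array `S x S x 3`.
#' @slot mask Logical `S x S` matrix of the pasted object mask.
#' @slot sourceScan Originating scan id.
#' @slot objectIndex 1-based object index within the scan.
#' @slot organ,classLabel Metadata carried from the scan.
#' @export
setClass("NormalizedObjectImage", representation(
  pixels = "array", mask = "matrix", sourceScan = "character",
  objectIndex = "integer", organ = "character", classLabel = "character"))

setValidity("NormalizedObjectImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3L] != 3L)
    return("pixels must be S x S x 3")
  if (dim(p)[1L] != dim(p)[2L]) return("canvas must be square")
  if (!identical(dim(object@mask), dim(p)[1:2]))
    return("mask must match canvas size")
  bg <- p * array(!object@mask, dim(p))
  if (any(bg != 0)) return("background pixels must be exactly 0")
  TRUE
})

#' AugmentationPolicy: geometric augmentation configuration
#'
#' @slot ops Subset of `rotate`, `shift`, `flip_vertical`, `mirror_horizontal`.
#' @slot rotateAngles Rotation angles in degrees.
#' @slot shiftMaxFraction Maximum shift as a fraction of canvas size, in
#'   `[0, 0.2]`.
#' @slot seed RNG seed.
#' @export
setClass("AugmentationPolicy", representation(
  ops = "character", rotateAngles = "numeric",
  shiftMaxFraction = "numeric", seed = "integer"))

setValidity("AugmentationPolicy", function(object) {
  known <- c("rotate", "shift", "flip_vertical", "mirror_horizontal")
  if (length(object@ops) < 1L) return("at least one op must be enabled")
  if (!all(object@ops %in% known))
    return(paste("unknown ops; allowed:", paste(known, collapse = ", ")))
  if (object@shiftMaxFraction < 0 || object@shiftMaxFraction > 0.2)
    return("shiftMaxFraction must lie in [0, 0.2]")
  if ("rotate" %in% object@ops && length(object@rotateAngles) < 1L)
    return("rotate enabled but no angles given")
  TRUE
})

#' Construct an AugmentationPolicy
#'
#' @param ops Enabled operations.
#' @param rotateAngles Rotation angles (degrees); multiples of 90 are exact,
#'   other angles use nearest-neighbour resampling.
#' @param shiftMaxFraction Maximum shift fraction of the canvas size.
#' @param seed RNG seed.
#' @return An [AugmentationPolicy-class].
#' @export
augmentationPolicy <- function(ops = c("rotate", "shift", "flip_vertical",
                                       "mirror_horizontal"),
                               rotateAngles = c(90, 180, 270),
                               shiftMaxFraction = 0.1, seed = 1L) {
  new("AugmentationPolicy", ops = ops, rotateAngles = rotateAngles,
      shiftMaxFraction = shiftMaxFraction, seed = as.integer(seed))
}

#' BackboneSpec: a backbone's input/layer contract
#'
#' @slot name Backbone name.
#' @slot inputSize Integer `(H, W, 3)` network input size.
#' @slot featureLayers Named integer vector mapping exportable layer names to
#'   their flattened output dimensionality.
#' @slot numClasses Number of classes of the classification head.
#' @slot headFeatureLayer Name of the layer feeding the classification head.
#' @export
setClass("BackboneSpec", representation(
  name = "character", inputSize = "integer", featureLayers = "integer",
  numClasses = "integer", headFeatureLayer = "character"))

setValidity("BackboneSpec", function(object) {
  if (length(object@inputSize) != 3L || object@inputSize[3L] != 3L)
    return("inputSize must be (H, W, 3)")
  if (is.null(names(object@featureLayers)))
    return("featureLayers must be named")
  if (object@numClasses < 2L) return("numClasses must be >= 2")
  TRUE
})

#' CnnModel: a backbone graph plus its spec
#'
#' Holds the layer graph (ordered node list with parameters) of one CNN
#' backbone together with its [BackboneSpec-class].
#'
#' @slot graph List of layer nodes in topological order.
#' @slot spec The [BackboneSpec-class].
#' @export
setClass("CnnModel", representation(graph = "list", spec = "BackboneSpec"))

#' TrainConfig: fine-tuning hyper-parameters
#'
#' Defaults follow the classical transfer-learning recipe used throughout the
#' package: batch size 32, learning rate 3e-4, validation every 64 steps.
#'
#' @slot batchSize,validationFrequency,maxEpochs Positive integers.
#' @slot learningRate Positive learning rate.
#' @slot freezePolicy `"freeze_all_conv"` (train the head only) or `"none"`.
#' @slot seed RNG seed.
#' @export
setClass("TrainConfig", representation(
  batchSize = "integer", learningRate = "numeric",
  validationFrequency = "integer", maxEpochs = "integer",
  freezePolicy = "character", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@batchSize < 1L || object@validationFrequency < 1L ||
      object@maxEpochs < 1L || object@learningRate <= 0)
    return("batchSize, validationFrequency, maxEpochs, learningRate must be positive")
  if (!object@freezePolicy %in% c("freeze_all_conv", "none"))
    return("freezePolicy must be 'freeze_all_conv' or 'none'")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param batchSize Mini-batch size.
#' @param learningRate SGD learning rate.
#' @param validationFrequency Steps between validation evaluations.
#' @param maxEpochs Number of epochs.
#' @param freezePolicy `"freeze_all_conv"` or `"none"`.
#' @param seed RNG seed.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(batchSize = 32L, learningRate = 3e-4,
                        validationFrequency = 64L, maxEpochs = 5L,
                        freezePolicy = "freeze_all_conv", seed = 1L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      learningRate = learningRate,
      validationFrequency = as.integer(validationFrequency),
      maxEpochs = as.integer(maxEpochs), freezePolicy = freezePolicy,
      seed = as.integer(seed))
}

#' FeatureSet: row-aligned deep feature matrix
#'
#' Extends [SummarizedExperiment::SummarizedExperiment-class]: the single
#' assay `"features"` holds a `d x n` matrix (features x samples), `colData`
#' carries the manifest rows the columns are aligned to, and metadata records
#' the backbone and layer the features came from. [featureMatrix()] returns
#' the conventional `n x d` orientation.
#'
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  if (!"features" %in% assayNames(object))
    return("assay 'features' is required")
  v <- assay(object, "features")
  if (!all(is.finite(v))) return("features must be finite")
  TRUE
})

#' Construct a FeatureSet
#'
#' @param values `n x d` numeric matrix (samples in rows).
#' @param rowIds Character ids aligned to rows of `values` (manifest paths).
#' @param layerName,backboneName Provenance of the features.
#' @param colData Optional data.frame of per-sample metadata (n rows).
#' @return A [FeatureSet-class].
#' @export
FeatureSet <- function(values, rowIds, layerName, backboneName,
                       colData = NULL) {
  values <- as.matrix(values)
  if (length(rowIds) != nrow(values))
    stopf("rowIds length (%d) must match rows of values (%d)",
          length(rowIds), nrow(values))
  if (!all(is.finite(values))) stopf("features must be finite")
  cd <- if (is.null(colData)) DataFrame(row.names = rowIds)
        else DataFrame(colData, row.names = rowIds)
  se <- SummarizedExperiment(
    assays = list(features = t(values)), colData = cd,
    metadata = list(layerName = layerName, backboneName = backboneName))
  new("FeatureSet", se)
}

#' PairingMap: pod-seed pairing of same-class samples
#'
#' @slot pairs data.frame with columns `podId`, `seedId`, `classLabel`.
#' @slot strategy Pairing strategy used.
#' @slot seed RNG seed used for random strategies.
#' @export
setClass("PairingMap", representation(
  pairs = "data.frame", strategy = "character", seed = "integer"))

setValidity("PairingMap", function(object) {
  p <- object@pairs
  if (!all(c("podId", "seedId", "classLabel") %in% names(p)))
    return("pairs needs columns podId, seedId, classLabel")
  if (anyDuplicated(paste(p$podId, p$seedId)))
    return("duplicated pod/seed pair")
  TRUE
})

#' FusedPairSet: concatenated pod+seed feature vectors with labels
#'
#' Row k is `c(podVector, seedVector)` for pair k (pod block first).
#'
#' @slot values `m x (dPod + dSeed)` matrix.
#' @slot labels Length-m class labels.
#' @slot pairing The [PairingMap-class] that produced the rows.
#' @slot podDim,seedDim Branch widths.
#' @export
setClass("FusedPairSet", representation(
  values = "matrix", labels = "character", pairing = "PairingMap",
  podDim = "integer", seedDim = "integer"))

setValidity("FusedPairSet", function(object) {
  if (ncol(object@values) != object@podDim + object@seedDim)
    return("column count must equal podDim + seedDim")
  if (nrow(object@values) != length(object@labels))
    return("labels must align with rows")
  TRUE
})

#' FusionClassifier: standardizer + SVM over fused features
#'
#' The per-dimension standardizer (mean/scale) is fitted on training pairs
#' only; the SVM is libsvm's one-vs-one C-classification via \pkg{e1071}.
#'
#' @slot fit The fitted `e1071::svm` object.
#' @slot kernel,cost SVM kernel and cost.
#' @slot center,scale Standardizer parameters (training data only).
#' @slot labels Class labels seen in training.
#' @slot featureDim Expected input width.
#' @export
setClass("FusionClassifier", representation(
  fit = "ANY", kernel = "character", cost = "numeric",
  center = "numeric", scale = "numeric", labels = "character",
  featureDim = "integer"))

#' ConfusionMatrix: K x K counts, rows = predicted, columns = true
#'
#' @slot countsMatrix Integer `K x K` matrix; `counts[p, t]` is the number of
#'   samples of true class `t` predicted as class `p`.
#' @slot classOrder Class label order of both dimensions.
#' @export
setClass("ConfusionMatrix", representation(
  countsMatrix = "matrix", classOrder = "character"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@countsMatrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (any(m < 0)) return("counts must be non-negative")
  if (nrow(m) != length(object@classOrder))
    return("classOrder must match matrix dimension")
  TRUE
})

#' MetricsReport: per-class and macro precision/recall/F1 plus accuracy
#'
#' @slot perClass data.frame with columns `class`, `precision`, `recall`,
#'   `f1`, `support`, `excluded`.
#' @slot macro Named numeric: macro precision/recall/f1.
#' @slot micro Named numeric: micro-averaged metrics.
#' @slot accuracy Overall accuracy (trace / total).
#' @export
setClass("MetricsReport", representation(
  perClass = "data.frame", macro = "numeric", micro = "numeric",
  accuracy = "numeric"))

#' GradCamMap: gradient-weighted class activation map
#'
#' @slot heatmap Layer-resolution map, min-max normalized to `[0, 1]`.
#' @slot overlayHeat Input-resolution bilinear upsampling of `heatmap`.
#' @slot overlay RGB blend of the input image and the heat map.
#' @slot targetClass,layerName Provenance.
#' @export
setClass("GradCamMap", representation(
  heatmap = "matrix", overlayHeat = "matrix", overlay = "array",
  targetClass = "character", layerName = "character"))

setValidity("GradCamMap", function(object) {
  h <- object@heatmap
  if (any(h < 0) || any(h > 1)) return("heatmap must lie in [0, 1]")
  TRUE
})

#' EmbeddingResult: t-SNE coordinates
#'
#' @slot coordsMatrix `n x 2` or `n x 3` coordinates, row-aligned with input.
#' @slot perplexity,seed t-SNE parameters.
#' @slot source Free-text description of the embedded features.
#' @export
setClass("EmbeddingResult", representation(
  coordsMatrix = "matrix", perplexity = "numeric", seed = "integer",
  source = "character"))

setValidity("EmbeddingResult", function(object) {
  if (!ncol(object@coordsMatrix) %in% c(2L, 3L))
    return("coords must be n x 2 or n x 3")
  if (!all(is.finite(object@coordsMatrix)))
    return("coordinates must be finite")
  TRUE
})

#' ClusterTree: hierarchical merge structure over class centroids
#'
#' Wraps an `hclust`-style merge list: `K - 1` merges for `K` leaves with
#' non-decreasing heights along the merge order (for the default
#' agglomerative method).
#'
#' @slot merge,height,order As in [stats::hclust].
#' @slot labels Leaf (class) labels.
#' @slot method Linkage or tree-construction method.
#' @export
setClass("ClusterTree", representation(
  merge = "matrix", height = "numeric", order = "integer",
  labels = "character", method = "character"))

setValidity("ClusterTree", function(object) {
  k <- length(object@labels)
  if (nrow(object@merge) != k - 1L) return("need K - 1 merges for K leaves")
  if (length(object@height) != k - 1L) return("heights must match merges")
  TRUE
})

## ------------------------------------------------------------------ accessors

#' @rdname PodSeedFusion-generics
#' @export
setMethod("pixels", "ScanImage", function(x) x@pixels)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("pixels", "NormalizedObjectImage", function(x) x@pixels)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("organ", "ScanImage", function(x) x@organ)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("organ", "NormalizedObjectImage", function(x) x@organ)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("classLabel", "ScanImage", function(x) x@classLabel)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("classLabel", "NormalizedObjectImage", function(x) x@classLabel)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("scanId", "ScanImage", function(x) x@scanId)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("scanId", "NormalizedObjectImage", function(x) x@sourceScan)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("objectMask", "BinaryMask", function(x) x@mask)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("objectMask", "NormalizedObjectImage", function(x) x@mask)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("objectMask", "ObjectROI", function(x) x@maskCrop)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("areaPx", "ObjectROI", function(x) x@areaPx)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("bbox", "ObjectROI", function(x) x@bbox)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("featureMatrix", "FeatureSet", function(x) t(assay(x, "features")))
#' @rdname PodSeedFusion-generics
#' @export
setMethod("featureMatrix", "FusedPairSet", function(x) x@values)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("rowIds", "FeatureSet", function(x) colnames(x))
#' @rdname PodSeedFusion-generics
#' @export
setMethod("layerName", "FeatureSet", function(x) metadata(x)$layerName)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("backboneName", "FeatureSet", function(x) metadata(x)$backboneName)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("featureLayers", "BackboneSpec", function(x) x@featureLayers)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("featureLayers", "CnnModel", function(x) x@spec@featureLayers)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("inputSize", "BackboneSpec", function(x) x@inputSize)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("inputSize", "CnnModel", function(x) x@spec@inputSize)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("numClasses", "BackboneSpec", function(x) x@numClasses)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("numClasses", "CnnModel", function(x) x@spec@numClasses)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("classOrder", "ConfusionMatrix", function(x) x@classOrder)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("counts", "ConfusionMatrix", function(x) x@countsMatrix)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("accuracy", "ConfusionMatrix",
          function(x) sum(diag(x@countsMatrix)) / sum(x@countsMatrix))
#' @rdname PodSeedFusion-generics
#' @export
setMethod("accuracy", "MetricsReport", function(x) x@accuracy)
#' @rdname PodSeedFusion-generics
#' @export
setMethod("coords", "EmbeddingResult", function(x) x@coordsMatrix)

## ----------------------------------------------------------------------- show

setMethod("show", "ScanImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ScanImage '%s' [%s/%s]: %d x %d RGB\n", object@scanId,
              object@classLabel, object@organ, d[1L], d[2L]))
})

setMethod("show", "NormalizedObjectImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("NormalizedObjectImage [%s/%s] %d x %d, object %d of scan '%s', %d fg px\n",
              object@classLabel, object@organ, d[1L], d[2L],
              object@objectIndex, object@sourceScan, sum(object@mask)))
})

setMethod("show", "ObjectROI", function(object) {
  cat(sprintf("ObjectROI bbox=(%d,%d,%d,%d) area=%d px\n",
              object@bbox[1L], object@bbox[2L], object@bbox[3L],
              object@bbox[4L], object@areaPx))
})

setMethod("show", "BackboneSpec", function(object) {
  cat(sprintf("BackboneSpec '%s': input %s, %d classes\n", object@name,
              paste(object@inputSize, collapse = "x"), object@numClasses))
  for (nm in names(object@featureLayers))
    cat(sprintf("  layer %-22s dim %d\n", nm, object@featureLayers[[nm]]))
})

setMethod("show", "CnnModel", function(object) {
  cat(sprintf("CnnModel '%s' with %d nodes\n", object@spec@name,
              length(object@graph)))
  show(object@spec)
})

setMethod("show", "FusedPairSet", function(object) {
  cat(sprintf("FusedPairSet: %d pairs x (%d pod + %d seed) dims, %d classes\n",
              nrow(object@values), object@podDim, object@seedDim,
              length(unique(object@labels))))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix over %d classes, %d samples, accuracy %.4f\n",
              length(object@classOrder), sum(object@countsMatrix),
              accuracy(object)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy %.4f | macro P %.4f R %.4f F1 %.4f (%d classes)\n",
              object@accuracy, object@macro[["precision"]],
              object@macro[["recall"]], object@macro[["f1"]],
              nrow(object@perClass)))
})

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree (%s) over %d leaves: %s\n", object@method,
              length(object@labels), paste(object@labels, collapse = ", ")))
})
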