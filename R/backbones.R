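## Backbone registry: AlexNet-, GoogLeNet-, ResNet18- and ResNet50-style
## graphs plus a small 64x64 test backbone. All are built with seeded random
## (He) initialization by default; classification heads are sized to
## numClasses. Exportable feature layers follow the classical transfer-
## learning choice of three layers per backbone: a late spatial activation,
## the global pooling (the fusion layer), and the softmax probabilities.
## Local-response normalization of the original AlexNet is omitted (it does
## not change any layer shape and modern practice drops it).

basicBlock <- function(gb, prefix, outC, stride = 1L) {
  inName <- gb$last
  inC <- gbShape(gb)[3L]
  gbConv(gb, paste0(prefix, "_branch2a"), 3L, outC, stride, 1L)
  gbBN(gb, paste0(prefix, "_bn2a"))
  gbRelu(gb, paste0(prefix, "_relu2a"))
  gbConv(gb, paste0(prefix, "_branch2b"), 3L, outC, 1L, 1L)
  gbBN(gb, paste0(prefix, "_bn2b"))
  main <- gb$last
  short <- inName
  if (stride != 1L || inC != outC) {
    gbConv(gb, paste0(prefix, "_branch1"), 1L, outC, stride, 0L, input = inName)
    gbBN(gb, paste0(prefix, "_bn1"))
    short <- gb$last
  }
  gbAddNode(gb, paste0(prefix, "_add"), c(main, short))
  gbRelu(gb, paste0(prefix, "_relu"))
}

bottleneckBlock <- function(gb, prefix, midC, stride, counter) {
  inName <- gb$last
  inC <- gbShape(gb)[3L]
  outC <- 4L * midC
  nextAct <- function() {
    counter$n <- counter$n + 1L
    sprintf("activation_%d_relu", counter$n)
  }
  gbConv(gb, paste0(prefix, "_branch2a"), 1L, midC, stride, 0L)
  gbBN(gb, paste0(prefix, "_bn2a"))
  gbRelu(gb, nextAct())
  gbConv(gb, paste0(prefix, "_branch2b"), 3L, midC, 1L, 1L)
  gbBN(gb, paste0(prefix, "_bn2b"))
  gbRelu(gb, nextAct())
  gbConv(gb, paste0(prefix, "_branch2c"), 1L, outC, 1L, 0L)
  gbBN(gb, paste0(prefix, "_bn2c"))
  main <- gb$last
  short <- inName
  if (stride != 1L || inC != outC) {
    gbConv(gb, paste0(prefix, "_branch1"), 1L, outC, stride, 0L, input = inName)
    gbBN(gb, paste0(prefix, "_bn1"))
    short <- gb$last
  }
  gbAddNode(gb, paste0(prefix, "_add"), c(main, short))
  gbRelu(gb, nextAct())
}

inceptionModule <- function(gb, prefix, p1, p3r, p3, p5r, p5, pp) {
  inName <- gb$last
  gbConv(gb, paste0(prefix, "_1x1"), 1L, p1, input = inName)
  gbRelu(gb, paste0(prefix, "_relu_1x1"))
  b1 <- gb$last
  gbConv(gb, paste0(prefix, "_3x3_reduce"), 1L, p3r, input = inName)
  gbRelu(gb, paste0(prefix, "_relu_3x3_reduce"))
  gbConv(gb, paste0(prefix, "_3x3"), 3L, p3, 1L, 1L)
  gbRelu(gb, paste0(prefix, "_relu_3x3"))
  b2 <- gb$last
  gbConv(gb, paste0(prefix, "_5x5_reduce"), 1L, p5r, input = inName)
  gbRelu(gb, paste0(prefix, "_relu_5x5_reduce"))
  gbConv(gb, paste0(prefix, "_5x5"), 5L, p5, 1L, 2L)
  gbRelu(gb, paste0(prefix, "_relu_5x5"))
  b3 <- gb$last
  gbMaxPool(gb, paste0(prefix, "_pool"), 3L, 1L, 1L, input = inName)
  gbConv(gb, paste0(prefix, "_pool_proj"), 1L, pp)
  gbRelu(gb, paste0(prefix, "_relu_pool_proj"))
  b4 <- gb$last
  gbConcat(gb, paste0(prefix, "-output"), c(b1, b2, b3, b4))
}

buildTiny <- function(numClasses) {
  gb <- newGraphBuilder(c(64L, 64L, 3L))
  gbConv(gb, "conv1", 3L, 16L, 1L, 1L); gbRelu(gb, "relu1")
  gbMaxPool(gb, "pool1", 2L, 2L)
  gbConv(gb, "conv2", 3L, 32L, 1L, 1L); gbRelu(gb, "relu2")
  gbMaxPool(gb, "pool2", 2L, 2L)
  gbConv(gb, "conv3", 3L, 64L, 1L, 1L); gbRelu(gb, "relu3")
  gbGap(gb, "avg_pool")
  gbFC(gb, "fc", numClasses)
  gbSoftmax(gb, "prob")
  list(gb = gb,
       layers = c(relu3 = 16L * 16L * 64L, avg_pool = 64L, prob = numClasses),
       head = "avg_pool")
}

buildAlexNet <- function(numClasses) {
  gb <- newGraphBuilder(c(227L, 227L, 3L))
  gbConv(gb, "conv1", 11L, 96L, 4L, 0L); gbRelu(gb, "relu1")
  gbMaxPool(gb, "pool1", 3L, 2L)
  gbConv(gb, "conv2", 5L, 256L, 1L, 2L); gbRelu(gb, "relu2")
  gbMaxPool(gb, "pool2", 3L, 2L)
  gbConv(gb, "conv3", 3L, 384L, 1L, 1L); gbRelu(gb, "relu3")
  gbConv(gb, "conv4", 3L, 384L, 1L, 1L); gbRelu(gb, "relu4")
  gbConv(gb, "conv5", 3L, 256L, 1L, 1L); gbRelu(gb, "relu5")
  gbMaxPool(gb, "pool5", 3L, 2L)
  gbFC(gb, "fc6", 4096L); gbRelu(gb, "relu6")
  gbFC(gb, "fc7", 4096L); gbRelu(gb, "relu7")
  gbFC(gb, "fc8", numClasses)
  gbSoftmax(gb, "prob")
  # fc8 is the retrained numClasses head; its printed-as-4096 form in some
  # published layer tables is inconsistent with a retrained head.
  list(gb = gb,
       layers = c(fc8 = numClasses, relu7 = 4096L, prob = numClasses),
       head = "relu7")
}

buildGoogLeNet <- function(numClasses) {
  gb <- newGraphBuilder(c(224L, 224L, 3L))
  gbConv(gb, "conv1-7x7_s2", 7L, 64L, 2L, 3L); gbRelu(gb, "conv1_relu")
  gbMaxPool(gb, "pool1-3x3_s2", 3L, 2L, 1L)
  gbConv(gb, "conv2-3x3_reduce", 1L, 64L); gbRelu(gb, "conv2_relu_reduce")
  gbConv(gb, "conv2-3x3", 3L, 192L, 1L, 1L); gbRelu(gb, "conv2_relu")
  gbMaxPool(gb, "pool2-3x3_s2", 3L, 2L, 1L)
  inceptionModule(gb, "inception_3a", 64L, 96L, 128L, 16L, 32L, 32L)
  inceptionModule(gb, "inception_3b", 128L, 128L, 192L, 32L, 96L, 64L)
  gbMaxPool(gb, "pool3-3x3_s2", 3L, 2L, 1L)
  inceptionModule(gb, "inception_4a", 192L, 96L, 208L, 16L, 48L, 64L)
  inceptionModule(gb, "inception_4b", 160L, 112L, 224L, 24L, 64L, 64L)
  inceptionModule(gb, "inception_4c", 128L, 128L, 256L, 24L, 64L, 64L)
  inceptionModule(gb, "inception_4d", 112L, 144L, 288L, 32L, 64L, 64L)
  inceptionModule(gb, "inception_4e", 256L, 160L, 320L, 32L, 128L, 128L)
  gbMaxPool(gb, "pool4-3x3_s2", 3L, 2L, 1L)
  inceptionModule(gb, "inception_5a", 256L, 160L, 320L, 32L, 128L, 128L)
  inceptionModule(gb, "inception_5b", 384L, 192L, 384L, 48L, 128L, 128L)
  gbGap(gb, "pool5-7x7_s1")
  gbFC(gb, "loss3-classifier", numClasses)
  gbSoftmax(gb, "prob")
  list(gb = gb,
       layers = c("inception_5b-output" = 7L * 7L * 1024L,
                  "pool5-7x7_s1" = 1024L, prob = numClasses),
       head = "pool5-7x7_s1")
}

buildResNet18 <- function(numClasses) {
  gb <- newGraphBuilder(c(224L, 224L, 3L))
  gbConv(gb, "conv1", 7L, 64L, 2L, 3L)
  gbBN(gb, "bn_conv1"); gbRelu(gb, "conv1_relu")
  gbMaxPool(gb, "pool1", 3L, 2L, 1L)
  widths <- c(64L, 128L, 256L, 512L)
  for (s in 1:4) {
    for (b in 1:2) {
      prefix <- sprintf("res%d%s", s + 1L, letters[b])
      basicBlock(gb, prefix, widths[s],
                 stride = if (s > 1L && b == 1L) 2L else 1L)
    }
  }
  gbGap(gb, "pool5")
  gbFC(gb, "fc", numClasses)
  gbSoftmax(gb, "prob")
  list(gb = gb,
       layers = c(res5b_relu = 7L * 7L * 512L, pool5 = 512L,
                  prob = numClasses),
       head = "pool5")
}

buildResNet50 <- function(numClasses) {
  gb <- newGraphBuilder(c(224L, 224L, 3L))
  counter <- new.env(); counter$n <- 0L
  gbConv(gb, "conv1", 7L, 64L, 2L, 3L)
  gbBN(gb, "bn_conv1")
  counter$n <- 1L
  gbRelu(gb, "activation_1_relu")
  gbMaxPool(gb, "pool1", 3L, 2L, 1L)
  blocks <- c(3L, 4L, 6L, 3L)
  mids <- c(64L, 128L, 256L, 512L)
  for (s in 1:4) {
    for (b in seq_len(blocks[s])) {
      prefix <- sprintf("res%d%s", s + 1L, letters[b])
      bottleneckBlock(gb, prefix, mids[s],
                      stride = if (s > 1L && b == 1L) 2L else 1L, counter)
    }
  }
  gbGap(gb, "avg_pool")
  gbFC(gb, "fc1000", numClasses)
  gbSoftmax(gb, "fc1000_softmax")
  # activation_48_relu is the 7x7x512 activation after the second conv of the
  # last bottleneck (the 49th and final ReLU is the block output).
  list(gb = gb,
       layers = c(activation_48_relu = 7L * 7L * 512L, avg_pool = 2048L,
                  fc1000_softmax = numClasses),
       head = "avg_pool")
}

backboneRegistry <- list(
  tiny = list(build = buildTiny, inputSize = c(64L, 64L, 3L)),
  alexnet = list(build = buildAlexNet, inputSize = c(227L, 227L, 3L)),
  googlenet = list(build = buildGoogLeNet, inputSize = c(224L, 224L, 3L)),
  resnet18 = list(build = buildResNet18, inputSize = c(224L, 224L, 3L)),
  resnet50 = list(build = buildResNet50, inputSize = c(224L, 224L, 3L)))

#' Registered backbone names
#' @return Character vector of backbone names accepted by [buildBackbone()].
#' @export
listBackbones <- function() names(backboneRegistry)

#' Build a CNN backbone
#'
#' Constructs one of the registered backbones (`alexnet`, `googlenet`,
#' `resnet18`, `resnet50`, or the small `tiny` test backbone) with its
#' classification head sized to `numClasses`. `weights = "random"` (the
#' default) draws seeded He-initialized weights and requires no download;
#' `weights = "pretrained"` loads parameter values from a local RDS file
#' (named list `nodeName -> list(W=, b=, gamma=, ...)`) supplied via
#' `weightsFile`, since no weights are bundled with the package.
#'
#' @param name Backbone name (see [listBackbones()]).
#' @param numClasses Number of output classes (head size).
#' @param weights `"random"` or `"pretrained"`.
#' @param seed RNG seed for random initialization.
#' @param weightsFile RDS file of parameters for `weights = "pretrained"`.
#' @return A [CnnModel-class]; its [BackboneSpec-class] declares the three
#'   exportable feature layers and their flattened dimensionalities.
#' @export
buildBackbone <- function(name, numClasses = 20L,
                          weights = c("random", "pretrained"), seed = 1L,
                          weightsFile = NULL) {
  weights <- match.arg(weights)
  if (!name %in% names(backboneRegistry))
    stopf("unknown backbone '%s'; registered: %s", name,
          paste(names(backboneRegistry), collapse = ", "))
  numClasses <- as.integer(numClasses)
  entry <- backboneRegistry[[name]]
  built <- withSeed(seed, entry$build(numClasses))
  graph <- built$gb$nodes
  if (weights == "pretrained") {
    if (is.null(weightsFile) || !file.exists(weightsFile))
      stopf(paste("pretrained weights are not bundled; supply weightsFile",
                  "(RDS of a named parameter list) or use weights='random'"))
    params <- readRDS(weightsFile)
    graph <- graphApplyDeltas(graphZero(graph, names(params)), params)
  }
  spec <- new("BackboneSpec", name = name, inputSize = entry$inputSize,
              featureLayers = vapply(built$layers, as.integer, integer(1L)),
              numClasses = numClasses, headFeatureLayer = built$head)
  new("CnnModel", graph = graph, spec = spec)
}

# zero out parameters of the named nodes so applyDeltas sets them outright
graphZero <- function(graph, nodeNames) {
  for (i in seq_along(graph)) {
    if (graph[[i]]$name %in% nodeNames) {
      for (p in intersect(names(graph[[i]]),
                          c("W", "b", "gamma", "beta", "mean", "var")))
        graph[[i]][[p]] <- graph[[i]][[p]] * 0
    }
  }
  graph
}

# name of the fc node fed (directly or via flatten) by the head feature layer
headNodeName <- function(model) {
  graph <- model@graph
  for (node in graph)
    if (node$type == "fc" && node$inputs == model@spec@headFeatureLayer)
      return(node$name)
  # fall back: last fc in the graph
  fcs <- vapply(graph, function(n)
    if (n$type == "fc") n$name else NA_character_, character(1L))
  fcs <- fcs[!is.na(fcs)]
  fcs[length(fcs)]
}
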