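## Analysis: Grad-CAM activation maps, exact t-SNE, and hierarchical
## clustering trees over class-level feature centroids with Newick export.

#' Gradient-weighted class activation map (Grad-CAM)
#'
#' Backpropagates the target class logit to the chosen spatial layer,
#' averages the gradient per channel to get channel weights, forms the
#' weighted sum of activation channels, applies ReLU and min-max normalizes
#' to `[0, 1]`. The map is bilinearly upsampled to input resolution and
#' blended over the (resized) input image.
#'
#' @param model A [CnnModel-class].
#' @param image [NormalizedObjectImage-class] or `H x W x 3` array.
#' @param layer Name of a layer with spatial activations.
#' @param targetClass Class index (1-based into the head outputs) or, when
#'   `classLevels` is given, a class label.
#' @param classLevels Optional class labels aligned with head outputs.
#' @param norm Channel normalization used at the input.
#' @param blend Overlay weight of the heat map in `[0, 1]`.
#' @return A [GradCamMap-class].
#' @export
gradCam <- function(model, image, layer, targetClass, classLevels = NULL,
                    norm = defaultNormalization(), blend = 0.5) {
  stopifnot(is(model, "CnnModel"))
  px <- if (is(image, "NormalizedObjectImage")) pixels(image) else image
  d <- inputSize(model)
  resized <- if (!identical(dim(px)[1:2], d[1:2]))
    resizeBilinear(px, d[1L], d[2L]) else px
  x <- preprocessImage(px, model@spec, norm)
  if (is.character(targetClass)) {
    if (is.null(classLevels)) stopf("classLevels needed for a label target")
    targetClass <- match(targetClass, classLevels)
  }
  K <- numClasses(model)
  if (is.na(targetClass) || targetClass < 1L || targetClass > K)
    stopf("targetClass out of range")
  cache <- nnForward(model, x)
  act <- cache$acts[[layer]]
  if (is.null(act)) stopf("no layer named '%s'", layer)
  if (length(dim(act)) != 3L)
    stopf("layer '%s' has no spatial activations", layer)
  logitNode <- headLogitNode(model)
  seed <- numeric(K)
  seed[targetClass] <- 1
  bp <- nnBackward(model, cache, stats::setNames(list(seed), logitNode),
                   needParams = FALSE, stopAt = layer)
  grad <- bp$dActs[[layer]]
  if (is.null(grad)) stopf("layer '%s' does not feed the classifier head", layer)
  w <- apply(grad, 3L, mean)
  cam <- pmax(apply(sweep(act, 3L, w, "*"), c(1L, 2L), sum), 0)
  rng <- range(cam)
  heat <- if (rng[2L] > rng[1L]) (cam - rng[1L]) / (rng[2L] - rng[1L])
          else cam * 0
  up <- resizeBilinear(heat, d[1L], d[2L])
  up <- clamp01(up)
  heatRGB <- array(0, dim(resized))
  heatRGB[, , 1L] <- up                       # red-hot overlay channel
  heatRGB[, , 3L] <- 1 - up
  overlay <- clamp01((1 - blend) * resized + blend * heatRGB)
  new("GradCamMap", heatmap = heat, overlayHeat = up, overlay = overlay,
      targetClass = as.character(targetClass), layerName = layer)
}

# node producing the head logits (input of the final softmax)
headLogitNode <- function(model) {
  graph <- model@graph
  last <- graph[[length(graph)]]
  if (last$type == "softmax") return(last$inputs)
  last$name
}

#' Exact t-SNE embedding
#'
#' Classic exact (O(n^2)) t-distributed stochastic neighbour embedding with
#' per-point perplexity calibration by binary search, early exaggeration and
#' momentum gradient descent. Deterministic given `seed`. Intended for the
#' feature-visualization scale of this package (hundreds of points or class
#' centroids), not for large n.
#'
#' @param features A [FeatureSet-class] or numeric matrix (rows = samples).
#' @param dims 2 or 3.
#' @param perplexity Target perplexity; requires `n > 3 * perplexity`.
#' @param seed RNG seed.
#' @param maxIter Gradient-descent iterations.
#' @param eta Learning rate.
#' @return An [EmbeddingResult-class].
#' @export
tsneEmbed <- function(features, dims = 2L, perplexity = 30,
                      seed = 1L, maxIter = 500L, eta = 100) {
  X <- if (is(features, "FeatureSet")) featureMatrix(features)
       else as.matrix(features)
  n <- nrow(X)
  if (!dims %in% c(2L, 3L)) stopf("dims must be 2 or 3")
  if (n <= 3 * perplexity)
    stopf("tsneEmbed: need n > 3 * perplexity (n = %d, perplexity = %g)", n,
          perplexity)
  D <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    Di <- D[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) { H <- 0; Pi <- Pi * 0 }
      else {
        H <- log(sumP) + beta * sum(Di * Pi) / sumP
        Pi <- Pi / sumP
      }
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) {
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withSeed(seed, {
    Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
  })
  dY <- Y * 0; gains <- Y * 0 + 1
  momentum <- 0.5
  Pex <- P * 4                                  # early exaggeration
  for (iter in seq_len(maxIter)) {
    if (iter == 101L) Pex <- P
    if (iter == 251L) momentum <- 0.8
    sumY <- rowSums(Y^2)
    d2 <- sweep(sweep(-2 * tcrossprod(Y), 1L, sumY, "+"), 2L, sumY, "+")
    num <- 1 / (1 + pmax(d2, 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pex - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  new("EmbeddingResult", coordsMatrix = Y, perplexity = perplexity,
      seed = as.integer(seed),
      source = if (is(features, "FeatureSet"))
        sprintf("%s/%s", backboneName(features), layerName(features))
      else "matrix")
}

#' Per-class centroids of a feature set
#'
#' @param x A [FusedPairSet-class], [FeatureSet-class] or matrix.
#' @param labels Class labels per row (taken from the object if omitted).
#' @return `K x d` matrix with class labels as row names.
#' @export
classCentroids <- function(x, labels = NULL) {
  if (is(x, "FusedPairSet")) {
    X <- x@values; labels <- x@labels
  } else if (is(x, "FeatureSet")) {
    X <- featureMatrix(x)
    if (is.null(labels)) labels <- colData(x)$class
  } else X <- as.matrix(x)
  if (is.null(labels)) stopf("labels required")
  cls <- sort(unique(as.character(labels)))
  out <- t(vapply(cls, function(cl)
    colMeans(X[labels == cl, , drop = FALSE]), numeric(ncol(X))))
  rownames(out) <- cls
  out
}

#' Hierarchical clustering tree over class centroids
#'
#' Builds a dendrogram over per-class mean feature vectors, read as a proxy
#' for genetic-relationship proximity between lines. The default is
#' agglomerative clustering (Ward on Euclidean distances) directly on the
#' centroids; `via3d = TRUE` first reduces the centroids to 3-D with
#' [tsneEmbed()] (which requires `K > 3 * perplexity`). An alternative
#' divisive mode recursively bisects classes with k-means.
#'
#' @param classFeatures `K x d` matrix of class centroids with class labels
#'   as row names (see [classCentroids()]).
#' @param via3d Reduce to 3-D by t-SNE before clustering.
#' @param linkage Linkage for [stats::hclust] (default `"ward.D2"`).
#' @param seed RNG seed (t-SNE and k-means).
#' @param perplexity t-SNE perplexity when `via3d = TRUE`; default
#'   `min(30, floor((K - 1) / 3))`.
#' @param method `"agglomerative"` or `"bisecting_kmeans"`.
#' @return A [ClusterTree-class].
#' @export
buildClusterTree <- function(classFeatures, via3d = FALSE,
                             linkage = "ward.D2", seed = 1L,
                             perplexity = NULL,
                             method = c("agglomerative", "bisecting_kmeans")) {
  method <- match.arg(method)
  X <- as.matrix(classFeatures)
  K <- nrow(X)
  if (K < 2L) stopf("need at least 2 classes")
  labels <- rownames(X)
  if (is.null(labels)) labels <- sprintf("class%02d", seq_len(K))
  if (via3d) {
    if (is.null(perplexity)) perplexity <- min(30, floor((K - 1) / 3))
    if (perplexity < 2) stopf("too few classes for via3d (need K > 6)")
    X <- coords(tsneEmbed(X, dims = 3L, perplexity = perplexity,
                          seed = seed))
  }
  if (method == "agglomerative") {
    hc <- hclust(dist(X), method = linkage)
    new("ClusterTree", merge = hc$merge, height = hc$height,
        order = as.integer(hc$order), labels = labels, method = linkage)
  } else {
    bisectingTree(X, labels, seed)
  }
}

# Divisive tree by recursive 2-means; merge heights are the within-cluster
# sum of squares of the cluster being split, so broader groups sit higher.
bisectingTree <- function(X, labels, seed) {
  K <- nrow(X)
  splits <- list()
  recurse <- function(idx, depth) {
    if (length(idx) == 1L) return(-idx)
    split <- tryCatch({
      km <- withSeed(childSeed(seed, depth * 131L + idx[1L]), {
        kmeans(X[idx, , drop = FALSE], centers = 2L, nstart = 5L)
      })
      list(a = idx[km$cluster == 1L], b = idx[km$cluster == 2L])
    }, error = function(e) list(a = integer(), b = integer()))
    a <- split$a; b <- split$b
    if (length(a) == 0L || length(b) == 0L) {     # degenerate (e.g. ties):
      a <- idx[seq_len(ceiling(length(idx) / 2))] # deterministic half split
      b <- setdiff(idx, a)
    }
    h <- sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2)
    left <- recurse(a, depth + 1L)
    right <- recurse(b, depth + 1L)
    splits[[length(splits) + 1L]] <<- list(left = left, right = right, h = h)
    length(splits)
  }
  recurse(seq_len(K), 1L)
  ord <- order(vapply(splits, function(s) s$h, numeric(1L)))
  rank <- match(seq_along(splits), ord)
  merge <- matrix(0L, K - 1L, 2L)
  height <- numeric(K - 1L)
  toRef <- function(v) if (v < 0L) v else rank[v]
  for (i in seq_along(splits)) {
    s <- splits[[ord[i]]]
    merge[i, ] <- c(toRef(s$left), toRef(s$right))
    height[i] <- s$h
  }
  hc <- list(merge = merge, height = height, labels = labels)
  ordr <- hclustLeafOrder(merge, K)
  new("ClusterTree", merge = merge, height = height,
      order = as.integer(ordr), labels = labels,
      method = "bisecting_kmeans")
}

hclustLeafOrder <- function(merge, K) {
  expand <- function(i)
    if (i < 0L) -i else c(expand(merge[i, 1L]), expand(merge[i, 2L]))
  expand(nrow(merge))
}

#' Convert a ClusterTree to hclust / export Newick
#'
#' @param tree A [ClusterTree-class].
#' @return `asHclust` returns a [stats::hclust] object.
#' @export
asHclust <- function(tree) {
  stopifnot(is(tree, "ClusterTree"))
  structure(list(merge = tree@merge, height = tree@height,
                 order = tree@order, labels = tree@labels,
                 method = tree@method, call = match.call(),
                 dist.method = "euclidean"),
            class = "hclust")
}

#' @rdname asHclust
#' @param path Output Newick file path.
#' @export
writeNewick <- function(tree, path) {
  phy <- ape::as.phylo(asHclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Height at which two leaves first share a cluster
#'
#' Useful for checking which class pairs merge earliest in the tree.
#'
#' @param tree A [ClusterTree-class].
#' @param a,b Leaf labels.
#' @return The merge height joining `a` and `b`.
#' @export
mergeHeight <- function(tree, a, b) {
  ia <- match(a, tree@labels); ib <- match(b, tree@labels)
  if (is.na(ia) || is.na(ib)) stopf("unknown leaf label")
  members <- lapply(seq_len(nrow(tree@merge)), function(i) {
    unlist(lapply(tree@merge[i, ], function(v)
      if (v < 0L) -v else NULL))
  })
  # accumulate leaf sets per merge row
  sets <- vector("list", nrow(tree@merge))
  for (i in seq_len(nrow(tree@merge))) {
    s <- integer()
    for (v in tree@merge[i, ])
      s <- c(s, if (v < 0L) -v else sets[[v]])
    sets[[i]] <- s
    if (ia %in% s && ib %in% s) return(tree@height[i])
  }
  stopf("leaves never merge (malformed tree)")
}
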