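## Fusion: pair pod and seed samples of the same class, concatenate their
## feature vectors (pod block first) and classify with an SVM.

#' Pair pod and seed samples of the same class
#'
#' The pairing step is plumbing the classical dual-branch workflow needs but
#' rarely states: pod and seed images are unrelated physical objects, so
#' same-class members must be matched explicitly. Strategies:
#' \describe{
#'   \item{round_robin (default)}{samples of each organ are sorted by path
#'     and pair `i` takes element `(i-1) mod n` of each list, cycling the
#'     shorter one; fully deterministic.}
#'   \item{random}{seeded sampling of distinct (pod, seed) combinations.}
#'   \item{exhaustive_capped}{all combinations in deterministic order, capped
#'     at `pairsPerClass`.}
#' }
#'
#' @param podManifest,seedManifest Manifest data.frames (one organ each).
#' @param split Split to pair (`"train"`, `"val"`, `"test"`), or `NULL` for
#'   all rows.
#' @param strategy Pairing strategy.
#' @param pairsPerClass Pairs per class; default the smaller organ count.
#' @param seed RNG seed for the random strategy.
#' @return A [PairingMap-class] whose ids are manifest paths.
#' @export
makePairs <- function(podManifest, seedManifest, split = NULL,
                      strategy = c("round_robin", "random",
                                   "exhaustive_capped"),
                      pairsPerClass = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  pick <- function(m) {
    if (!is.null(split)) m <- m[m$split == split, , drop = FALSE]
    m
  }
  pods <- pick(podManifest)
  seeds <- pick(seedManifest)
  classes <- sort(unique(c(pods$class, seeds$class)))
  missing <- classes[!(classes %in% pods$class & classes %in% seeds$class)]
  if (length(missing))
    stopf("class present in one organ only: %s",
          paste(missing, collapse = ", "))
  rows <- list()
  withSeed(seed, {
    for (cl in classes) {
      podIds <- sort(pods$path[pods$class == cl])
      seedIds <- sort(seeds$path[seeds$class == cl])
      nP <- length(podIds); nS <- length(seedIds)
      ppc <- if (is.null(pairsPerClass)) min(nP, nS) else pairsPerClass
      ij <- switch(strategy,
        round_robin = cbind((seq_len(ppc) - 1L) %% nP + 1L,
                            (seq_len(ppc) - 1L) %% nS + 1L),
        random = {
          if (ppc > nP * nS)
            stopf("pairsPerClass (%d) exceeds %d distinct pairs for class %s",
                  ppc, nP * nS, cl)
          k <- sample.int(nP * nS, ppc) - 1L
          cbind(k %% nP + 1L, k %/% nP + 1L)
        },
        exhaustive_capped = {
          k <- seq_len(min(ppc, nP * nS)) - 1L
          cbind(k %% nP + 1L, k %/% nP + 1L)
        })
      rows[[cl]] <- data.frame(podId = podIds[ij[, 1L]],
                               seedId = seedIds[ij[, 2L]],
                               classLabel = cl, stringsAsFactors = FALSE)
    }
  })
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  new("PairingMap", pairs = pairs, strategy = strategy,
      seed = as.integer(seed))
}

#' Concatenate pod and seed features along a pairing
#'
#' Row `k` of the result is `c(podVector, seedVector)` for pair `k` (pod
#' block first), giving fused width `dPod + dSeed` (e.g. 2048 + 2048 = 4096
#' for two global-average-pool branches).
#'
#' @param podFeatures,seedFeatures [FeatureSet-class] objects covering all
#'   ids of the pairing.
#' @param pairing A [PairingMap-class].
#' @return A [FusedPairSet-class].
#' @export
fuseFeatures <- function(podFeatures, seedFeatures, pairing) {
  p <- pairing@pairs
  iP <- match(p$podId, rowIds(podFeatures))
  iS <- match(p$seedId, rowIds(seedFeatures))
  if (anyNA(iP) || anyNA(iS))
    stopf("pairing refers to %d pod / %d seed ids missing from the feature sets",
          sum(is.na(iP)), sum(is.na(iS)))
  Xp <- featureMatrix(podFeatures)[iP, , drop = FALSE]
  Xs <- featureMatrix(seedFeatures)[iS, , drop = FALSE]
  new("FusedPairSet", values = cbind(Xp, Xs),
      labels = as.character(p$classLabel), pairing = pairing,
      podDim = ncol(Xp), seedDim = ncol(Xs))
}

#' Train the SVM classifier on fused features
#'
#' Fits a per-dimension z-score standardizer on the training pairs only,
#' then a one-vs-one C-classification SVM (libsvm via \pkg{e1071}) on the
#' standardized features. A linear kernel is the default for these
#' high-dimensional deep features.
#'
#' @param train A [FusedPairSet-class] (or plain matrix with `labels`).
#' @param kernel `"linear"` or `"radial"`.
#' @param cost SVM cost parameter C.
#' @param labels Class labels if `train` is a matrix.
#' @return A [FusionClassifier-class].
#' @export
trainFusionClassifier <- function(train, kernel = c("linear", "radial"),
                                  cost = 1, labels = NULL) {
  kernel <- match.arg(kernel)
  X <- if (is(train, "FusedPairSet")) train@values else as.matrix(train)
  y <- if (is(train, "FusedPairSet")) train@labels else as.character(labels)
  if (length(unique(y)) < 2L)
    stopf("training data must contain at least 2 classes")
  if (min(table(y)) < 2L)
    stopf("every class needs at least 2 training samples")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  fit <- e1071::svm(Xs, factor(y), kernel = kernel, cost = cost,
                    scale = FALSE)
  new("FusionClassifier", fit = fit, kernel = kernel, cost = cost,
      center = ctr, scale = scl, labels = sort(unique(y)),
      featureDim = ncol(X))
}

#' Predict class labels for fused pairs
#'
#' @param object A [FusionClassifier-class].
#' @param newdata A [FusedPairSet-class] or matrix of matching width.
#' @param ... Ignored.
#' @return Character vector of predicted labels, one per row.
#' @export
setMethod("predict", "FusionClassifier", function(object, newdata, ...) {
  X <- if (is(newdata, "FusedPairSet")) newdata@values else as.matrix(newdata)
  if (ncol(X) != object@featureDim)
    stopf("feature width %d does not match training width %d", ncol(X),
          object@featureDim)
  Xs <- sweep(sweep(X, 2L, object@center), 2L, object@scale, "/")
  as.character(predict(object@fit, Xs))
})
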