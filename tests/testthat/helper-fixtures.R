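# Shared fixtures, all generated in code.

# A labelled canvas image: solid-colour disk on black, with mild noise.
diskImage <- function(size = 64L, colour = c(1, 0, 0), radius = size / 5,
                      noise = 0.02, label = "A", seed = NULL) {
  gen <- function() {
    px <- array(0, c(size, size, 3L))
    ctr <- (size + 1) / 2
    g <- expand.grid(r = seq_len(size), c = seq_len(size))
    mask <- matrix((g$r - ctr)^2 + (g$c - ctr)^2 <= radius^2, size, size)
    for (ch in 1:3) {
      plane <- matrix(0, size, size)
      plane[mask] <- pmin(pmax(colour[ch] + runif(sum(mask), -noise, noise),
                               0.05), 1)
      px[, , ch] <- plane
    }
    new("NormalizedObjectImage", pixels = px, mask = mask,
        sourceScan = "fixture", objectIndex = 1L, organ = "seed",
        classLabel = label)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# n images per class for a linearly separable multi-class set
separableImageSet <- function(nPerClass = 8L, seed = 42L,
                              radiusRange = c(10, 16),
                              colours = list(A = c(0.9, 0.1, 0.1),
                                             B = c(0.1, 0.9, 0.1),
                                             C = c(0.1, 0.2, 0.9))) {
  withr::with_seed(seed, {
    out <- list()
    for (lab in names(colours))
      for (i in seq_len(nPerClass))
        out[[length(out) + 1L]] <- diskImage(
          colour = colours[[lab]],
          radius = runif(1, radiusRange[1], radiusRange[2]), label = lab)
    out
  })
}

# Brute-force precision/recall/F1 oracle by direct pair counting.
bruteForcePRF <- function(trueL, predL, classes) {
  t(vapply(classes, function(k) {
    tp <- sum(predL == k & trueL == k)
    fp <- sum(predL == k & trueL != k)
    fn <- sum(predL != k & trueL == k)
    P <- if (tp + fp == 0) 0 else tp / (tp + fp)
    R <- if (tp + fn == 0) 0 else tp / (tp + fn)
    F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
    c(precision = P, recall = R, f1 = F1)
  }, numeric(3L)))
}

# Mean silhouette of points under integer labels (euclidean).
meanSilhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1L)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Small manifest of object images on disk for augmentation tests.
writeObjectFixtures <- function(dir, classes = c("A", "B"), nPerClass = 6L,
                                size = 48L, seed = 7L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  withr::with_seed(seed, {
    for (cl in classes) {
      colour <- runif(3, 0.3, 1)
      for (i in seq_len(nPerClass)) {
        img <- diskImage(size = size, colour = colour,
                         radius = runif(1, 6, 10), label = cl)
        path <- file.path(dir, sprintf("%s_seed_fix_%03d.png", cl, i))
        writeImageFile(pixels(img), path)
        rows[[length(rows) + 1L]] <- data.frame(
          path = path, class = cl, organ = "seed",
          scan_id = sprintf("fix_%s", cl), object_index = i,
          area_px = sum(objectMask(img)), split = "unassigned",
          stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}

# Run the small end-to-end synthetic pipeline and return the report.
runSmallPipeline <- function(seed, K = 6L, perClassScans = 3L,
                             objectsPerScan = 8L, nSiblingPairs = 0L,
                             complementarity = 0, outputRoot = tempfile(),
                             analyze = TRUE, siblingDelta = 0.015) {
  cfg <- pipelineConfig(list(
    runName = sprintf("s%d", seed), outputRoot = outputRoot,
    seed = as.integer(seed),
    synthetic = list(K = as.integer(K),
                     perClassScans = as.integer(perClassScans),
                     objectsPerScan = as.integer(objectsPerScan),
                     nSiblingPairs = as.integer(nSiblingPairs),
                     complementarity = complementarity,
                     siblingDelta = siblingDelta),
    analyze = list(enabled = analyze)))
  suppressMessages(runPipeline(cfg))
}
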