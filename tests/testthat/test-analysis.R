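test_that("Grad-CAM maps have layer resolution and analytic structure", {
  model <- buildBackbone("tiny", numClasses = 3L, seed = 2)
  im <- diskImage(seed = 14)
  g <- gradCam(model, im, layer = "relu3", targetClass = 1L)
  expect_identical(dim(g@heatmap), c(16L, 16L))        # layer spatial size
  expect_identical(dim(g@overlayHeat), c(64L, 64L))
  expect_true(all(g@heatmap >= 0 & g@heatmap <= 1))

  # constant-zero head: gradient vanishes, map is all zero after ReLU
  zeroed <- model
  zeroed@graph <- PodSeedFusion:::graphSetParams(
    zeroed@graph, "fc",
    list(W = PodSeedFusion:::graphNode(model@graph, "fc")$W * 0,
         b = rep(0, 3)))
  g0 <- gradCam(zeroed, im, layer = "relu3", targetClass = 1L)
  expect_true(all(g0@heatmap == 0))

  # single positive-weight channel: heat map equals that channel's
  # normalized activation at the pooled layer's source
  onehot <- model
  W <- PodSeedFusion:::graphNode(model@graph, "fc")$W * 0
  W[17L, 1L] <- 1                                       # only channel 17
  onehot@graph <- PodSeedFusion:::graphSetParams(onehot@graph, "fc",
                                                 list(W = W, b = rep(0, 3)))
  g1 <- gradCam(onehot, im, layer = "relu3", targetClass = 1L)
  px <- PodSeedFusion:::preprocessImage(pixels(im), model@spec)
  act <- PodSeedFusion:::getActivation(
    PodSeedFusion:::nnForward(model, px, upto = "relu3"), "relu3")
  chan <- act[, , 17L]
  expected <- if (max(chan) > min(chan))
    (chan - min(chan)) / (max(chan) - min(chan)) else chan * 0
  expect_equal(g1@heatmap, expected, tolerance = 1e-9)

  expect_error(gradCam(model, im, layer = "avg_pool", targetClass = 1L),
               "no spatial activations")
})

test_that("Grad-CAM heat concentrates on the object for a trained head", {
  # objects at a realistic fraction of the input frame (~25% mask area);
  # for much smaller objects the receptive-field halo dilutes the fraction
  imgs <- separableImageSet(nPerClass = 8L, radiusRange = c(16, 22))
  model <- buildBackbone("tiny", numClasses = 3L, seed = 5)
  ft <- finetuneBackbone(model, imgs, imgs[seq(1, 24, by = 6)],
                         trainConfig(batchSize = 8L, learningRate = 0.5,
                                     maxEpochs = 4L,
                                     validationFrequency = 5L, seed = 2L))
  fracs <- vapply(imgs[seq(1, 24, by = 2)], function(im) {
    g <- gradCam(ft$model, im,
                 layer = "relu3",
                 targetClass = match(classLabel(im), ft$classLevels))
    mask <- PodSeedFusion:::resizeBilinear(objectMask(im) * 1, 64L, 64L) > 0.5
    sum(g@overlayHeat[mask]) / max(sum(g@overlayHeat), 1e-9)
  }, numeric(1))
  expect_gte(mean(fracs), 0.6)
})

test_that("t-SNE separates well-separated clusters deterministically", {
  withr::with_seed(8, {
    X <- rbind(matrix(rnorm(25 * 8), ncol = 8),
               matrix(rnorm(25 * 8, mean = 10), ncol = 8))
  })
  lab <- rep(1:2, each = 25)
  emb <- tsneEmbed(X, dims = 2L, perplexity = 8, seed = 3)
  expect_identical(dim(coords(emb)), c(50L, 2L))
  expect_gt(meanSilhouette(coords(emb), lab), 0.5)
  emb2 <- tsneEmbed(X, dims = 2L, perplexity = 8, seed = 3)
  expect_identical(coords(emb), coords(emb2))
  emb3 <- tsneEmbed(X, dims = 3L, perplexity = 8, seed = 3)
  expect_identical(ncol(coords(emb3)), 3L)
  expect_error(tsneEmbed(X[1:10, ], perplexity = 8), "n > 3")
})

test_that("cluster trees merge near-duplicates first", {
  # two identical centroids merge first at height 0
  X <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5), d = c(9, 1))
  tr <- buildClusterTree(X)
  expect_identical(sort(tr@merge[1, ]), c(-2L, -1L))
  expect_equal(tr@height[1], 0)
  expect_identical(nrow(tr@merge), 3L)                 # K - 1 merges

  # three collinear centroids at 0, 1, 10: first merge is {0, 1}
  X2 <- matrix(c(0, 1, 10), ncol = 1,
               dimnames = list(c("p0", "p1", "p10"), NULL))
  tr2 <- buildClusterTree(X2)
  expect_identical(sort(tr2@merge[1, ]), c(-2L, -1L))
  expect_lt(mergeHeight(tr2, "p0", "p1"), mergeHeight(tr2, "p0", "p10"))
  expect_error(buildClusterTree(X2[1, , drop = FALSE]), "at least 2")
})

test_that("cluster tree variants and Newick export interoperate", {
  withr::with_seed(10, {
    X <- matrix(rnorm(20 * 6), 20, 6)
  })
  rownames(X) <- sprintf("L%02d", 1:20)
  X[2, ] <- X[1, ] + 0.01                             # sibling-like pair
  tr <- buildClusterTree(X, via3d = TRUE, seed = 4)
  expect_identical(length(tr@labels), 20L)
  expect_identical(sort(tr@merge[1, ]), c(-2L, -1L))  # duplicates still first
  nw <- tempfile(fileext = ".nwk")
  writeNewick(tr, nw)
  phy <- ape::read.tree(nw)
  expect_setequal(phy$tip.label, rownames(X))

  trb <- buildClusterTree(X, method = "bisecting_kmeans", seed = 6)
  expect_identical(nrow(trb@merge), 19L)
  hc <- asHclust(trb)
  expect_s3_class(hc, "hclust")
  expect_identical(sort(hc$order), 1:20)
})
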