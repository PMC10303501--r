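mkOrganManifest <- function(n, classes, organ, split = "test") {
  do.call(rbind, lapply(classes, function(cl)
    data.frame(path = sprintf("%s/%s_%03d.png", organ, cl, seq_len(n)),
               class = cl, organ = organ, scan_id = "s",
               object_index = seq_len(n), area_px = 10L, split = split,
               stringsAsFactors = FALSE)))
}

test_that("round-robin pairing cycles the shorter organ deterministically", {
  pods <- mkOrganManifest(4L, c("A", "B"), "pod")
  seeds <- mkOrganManifest(4L, c("A", "B"), "seed")
  pm <- makePairs(pods, seeds, split = "test")
  pa <- pm@pairs[pm@pairs$classLabel == "A", ]
  expect_identical(nrow(pa), 4L)
  expect_identical(basename(pa$podId), sprintf("A_%03d.png", 1:4))
  expect_identical(basename(pa$seedId), sprintf("A_%03d.png", 1:4))

  # 3 pods, 5 seeds, 5 pairs: pod indices cycle mod 3
  pods2 <- mkOrganManifest(3L, "A", "pod")
  seeds2 <- mkOrganManifest(5L, "A", "seed")
  pm2 <- makePairs(pods2, seeds2, split = "test", pairsPerClass = 5L)
  expect_identical(basename(pm2@pairs$podId),
                   sprintf("A_%03d.png", c(1, 2, 3, 1, 2)))
  expect_identical(basename(pm2@pairs$seedId), sprintf("A_%03d.png", 1:5))
})

test_that("random pairing is seeded, duplicate-free, and bounded", {
  pods <- mkOrganManifest(6L, c("A", "B"), "pod")
  seeds <- mkOrganManifest(6L, c("A", "B"), "seed")
  p1 <- makePairs(pods, seeds, split = "test", strategy = "random",
                  pairsPerClass = 10L, seed = 5)
  p2 <- makePairs(pods, seeds, split = "test", strategy = "random",
                  pairsPerClass = 10L, seed = 5)
  expect_identical(p1@pairs, p2@pairs)
  expect_false(anyDuplicated(paste(p1@pairs$podId, p1@pairs$seedId)) > 0)
  expect_error(makePairs(pods, seeds, split = "test", strategy = "random",
                         pairsPerClass = 100L), "exceeds")
  # class present in one organ only is a data error
  expect_error(makePairs(pods, mkOrganManifest(3L, "A", "seed"),
                         split = "test"), "one organ only")
})

test_that("fusion concatenates pod block first with aligned rows", {
  pods <- mkOrganManifest(3L, c("A", "B"), "pod")
  seeds <- mkOrganManifest(3L, c("A", "B"), "seed")
  withr::with_seed(2, {
    Xp <- matrix(rnorm(6 * 4), 6, 4)
    Xs <- matrix(rnorm(6 * 3), 6, 3)
  })
  fp <- FeatureSet(Xp, pods$path, "lp", "tiny")
  fs <- FeatureSet(Xs, seeds$path, "ls", "tiny")
  pm <- makePairs(pods, seeds, split = "test")
  fused <- fuseFeatures(fp, fs, pm)
  expect_identical(ncol(featureMatrix(fused)), 7L)
  expect_identical(fused@podDim, 4L)
  # identity pairing: column means concatenate branch column means
  expect_equal(colMeans(featureMatrix(fused)),
               c(colMeans(Xp[order(pods$path), ]),
                 colMeans(Xs[order(seeds$path), ])), tolerance = 1e-12)
  # zero pod branch leaves the seed block intact
  f0 <- fuseFeatures(FeatureSet(Xp * 0, pods$path, "lp", "tiny"), fs, pm)
  expect_true(all(featureMatrix(f0)[, 1:4] == 0))
  expect_equal(featureMatrix(f0)[, 5:7], featureMatrix(fused)[, 5:7])
  # missing ids are a data error
  expect_error(fuseFeatures(FeatureSet(Xp[1:3, ], pods$path[1:3], "l", "t"),
                            fs, pm), "missing")
})

gaussianFixture <- function(nPerClass = 20L, d = 10L, sep = 6, seed = 3L) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(nPerClass * d), ncol = d),
               matrix(rnorm(nPerClass * d, mean = sep), ncol = d))
  })
  list(X = X, y = rep(c("A", "B"), each = nPerClass))
}

test_that("SVM classifier: separable fit, duplication invariance, determinism", {
  fx <- gaussianFixture()
  clf <- trainFusionClassifier(fx$X, labels = fx$y)
  expect_identical(predict(clf, fx$X), fx$y)
  # duplicating every training point leaves the decision function unchanged
  clf2 <- trainFusionClassifier(rbind(fx$X, fx$X),
                                labels = c(fx$y, fx$y))
  withr::with_seed(9, {
    grid <- rbind(matrix(rnorm(100 * ncol(fx$X), mean = 0), 100),
                  matrix(rnorm(100 * ncol(fx$X), mean = 6), 100))
  })
  expect_identical(predict(clf, grid), predict(clf2, grid))
  # same data twice: identical support-vector count
  clf3 <- trainFusionClassifier(fx$X, labels = fx$y)
  expect_identical(nrow(clf@fit$SV), nrow(clf3@fit$SV))
  # row independence: permuted rows give permuted predictions
  perm <- withr::with_seed(4, sample(nrow(grid)))
  expect_identical(predict(clf, grid[perm, ]), predict(clf, grid)[perm])
  # single row still predicts
  expect_length(predict(clf, grid[1, , drop = FALSE]), 1L)
  # errors
  expect_error(trainFusionClassifier(fx$X, labels = rep("A", nrow(fx$X))),
               "2 classes")
  expect_error(predict(clf, grid[, 1:3]), "width")
})

test_that("standardizer is fitted on training data only", {
  fx <- gaussianFixture()
  clf <- trainFusionClassifier(fx$X, labels = fx$y)
  expect_equal(clf@center, colMeans(fx$X), tolerance = 1e-12)
  withr::with_seed(11, {
    testX <- matrix(rnorm(50 * ncol(fx$X), mean = 3, sd = 20), 50)
  })
  # predictions for given rows cannot depend on what else is in the test
  # batch: the standardizer is frozen, never refit on new data
  base <- predict(clf, testX)
  expect_identical(predict(clf, rbind(testX, testX * 100))[1:50], base)
})
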