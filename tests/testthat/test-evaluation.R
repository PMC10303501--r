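test_that("confusion matrix counts predicted x true", {
  cm <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  m <- counts(cm)
  expect_identical(m["A", "A"], 1L)   # rows = predicted, columns = true
  expect_identical(m["B", "A"], 1L)
  expect_identical(m["B", "B"], 1L)
  expect_identical(m["A", "B"], 0L)
  expect_identical(sum(m), 3L)

  # perfect predictions give a diagonal matrix
  y <- rep(c("A", "B", "C"), times = c(5, 3, 2))
  cmd <- confusionMatrix(y, y)
  expect_identical(unname(diag(counts(cmd))), c(5L, 3L, 2L))
  expect_identical(sum(counts(cmd)) - sum(diag(counts(cmd))), 0L)
  expect_identical(accuracy(cmd), 1)

  # column sums equal class frequencies in the true labels
  withr::with_seed(6, {
    truth <- sample(c("A", "B", "C"), 60, replace = TRUE)
    pred <- sample(c("A", "B", "C"), 60, replace = TRUE)
  })
  cmr <- confusionMatrix(truth, pred)
  expect_equal(unname(colSums(counts(cmr))),
               as.numeric(table(factor(truth, c("A", "B", "C")))))
  expect_error(confusionMatrix(truth, pred, classOrder = c("A", "B")),
               "not in classOrder")
})

test_that("precision/recall/F1 match the formulas and the counting oracle", {
  # identity matrix: all metrics 1
  y <- rep(c("A", "B", "C"), each = 4)
  rep1 <- precisionRecallF1(confusionMatrix(y, y))
  expect_true(all(rep1@perClass[, c("precision", "recall", "f1")] == 1))
  expect_identical(unname(rep1@macro["f1"]), 1)

  # symmetric 2-class case evaluates to 0.8 everywhere
  truth <- rep(c("A", "B"), each = 10)
  pred <- c(rep("A", 8), rep("B", 2), rep("A", 2), rep("B", 8))
  rep2 <- precisionRecallF1(confusionMatrix(truth, pred))
  expect_equal(as.numeric(unlist(
    rep2@perClass[, c("precision", "recall", "f1")])), rep(0.8, 6))
  expect_identical(rep2@accuracy, 0.8)

  # oracle equivalence on 100 random label vectors
  withr::with_seed(99, {
    for (i in 1:100) {
      K <- sample(2:6, 1)
      classes <- LETTERS[seq_len(K)]
      n <- sample(10:60, 1)
      truth <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
      r <- suppressWarnings(
        precisionRecallF1(confusionMatrix(truth, pred, classes)))
      oracle <- bruteForcePRF(truth, pred, classes)
      expect_equal(as.matrix(r@perClass[, c("precision", "recall", "f1")]),
                   oracle, tolerance = 1e-12, ignore_attr = TRUE)
      # accuracy is the trace over the total; F1 within [0, max(P, R)]
      expect_equal(r@accuracy, mean(truth == pred), tolerance = 1e-12)
      expect_true(all(r@perClass$f1 >= 0))
      expect_true(all(r@perClass$f1 <=
                        pmax(r@perClass$precision, r@perClass$recall) + 1e-12))
    }
  })
})

test_that("empty classes use the 0/0 -> 0 convention with a warning", {
  cm <- confusionMatrix(c("A", "A"), c("A", "A"), c("A", "B"))
  w <- capture_warnings(r <- precisionRecallF1(cm))
  expect_length(w, 2L)                    # precision and recall both warn
  expect_true(all(grepl("0/0", w)))
  pc <- r@perClass
  expect_identical(pc$precision[pc$class == "B"], 0)
  expect_identical(pc$recall[pc$class == "B"], 0)
  expect_true(pc$excluded[pc$class == "B"])
  expect_false(pc$excluded[pc$class == "A"])
})

test_that("replicate summary computes mean and standard error", {
  expect_equal(replicateSummary(c(1, 1, 1))[c("mean", "se")],
               c(mean = 1, se = 0))
  vals <- c(89.90, 87.90, 88.70)
  r <- replicateSummary(vals)
  # independent recomputation of the sample-SD convention
  m <- sum(vals) / 3
  sdev <- sqrt(sum((vals - m)^2) / 2)
  expect_equal(unname(r["mean"]), m, tolerance = 1e-12)
  expect_equal(unname(r["se"]), sdev / sqrt(3), tolerance = 1e-12)
  rp <- replicateSummary(vals, convention = "population")
  expect_equal(unname(rp["se"]), sqrt(sum((vals - m)^2) / 3) / sqrt(3),
               tolerance = 1e-12)
  # shift invariance
  r2 <- replicateSummary(vals + 5)
  expect_equal(unname(r2["mean"]), m + 5, tolerance = 1e-12)
  expect_equal(unname(r2["se"]), unname(r["se"]), tolerance = 1e-12)
  expect_error(replicateSummary(1), "at least 2")
})

test_that("metrics and heatmap exports are written", {
  truth <- rep(c("A", "B"), each = 6)
  pred <- c(rep("A", 5), "B", rep("B", 5), "A")
  cm <- confusionMatrix(truth, pred)
  rep <- precisionRecallF1(cm)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  hp <- tempfile(fileext = ".png")
  writeMetrics(rep, cm, jsonPath = jp, csvPath = cp)
  writeConfusionHeatmap(cm, hp)
  expect_true(all(file.exists(jp, cp, hp)))
  parsed <- jsonlite::read_json(jp)
  expect_equal(parsed$accuracy, rep@accuracy, tolerance = 1e-9)
  expect_identical(dim(png::readPNG(hp))[1:2], c(24L, 24L))
})
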