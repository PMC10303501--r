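test_that("phenotype generation encodes siblings and complementary pairs", {
  g <- generatePhenotypes(20, nSiblingPairs = 2, complementarity = 1,
                          seed = 12)
  phen <- g$phenotypes
  expect_identical(nrow(phen), 20L)
  expect_identical(nrow(g$siblings), 2L)

  # sibling seed-parameter distance far below typical inter-class distance
  seedVec <- function(i) {
    p <- phen$seedParams[[i]]
    c(p$axisA, p$axisB, p$rgb)
  }
  M <- t(vapply(seq_len(20), seedVec, numeric(5)))
  Ms <- scale(M)
  Ms[, attr(Ms, "scaled:scale") == 0] <- 0
  D <- as.matrix(dist(Ms))
  sibIdx <- cbind(match(g$siblings$classA, phen$class),
                  match(g$siblings$classB, phen$class))
  interD <- D[upper.tri(D)]
  for (r in seq_len(nrow(sibIdx)))
    expect_lt(D[sibIdx[r, 1], sibIdx[r, 2]], 0.1 * median(interD))

  # complementarity = 1: every non-sibling pair identical in one organ
  comp <- phen[phen$role == "complementary", ]
  expect_gt(nrow(comp), 0L)
  for (i in seq_len(nrow(comp))) {
    self <- match(comp$class[i], phen$class)
    partner <- match(comp$partner[i], phen$class)
    if (comp$informativeOrgan[i] == "pod")
      expect_identical(phen$seedParams[[self]], phen$seedParams[[partner]])
    else
      expect_identical(phen$podParams[[self]], phen$podParams[[partner]])
  }

  # determinism and input validation
  expect_identical(generatePhenotypes(20, 2, 1, seed = 12)$phenotypes$class,
                   phen$class)
  expect_error(generatePhenotypes(1), ">= 2")
  expect_error(generatePhenotypes(4, nSiblingPairs = 3), "<= K")
})

test_that("scan rendering matches its ground truth", {
  g <- generatePhenotypes(3, seed = 33)
  # empty scan is pure black
  r0 <- renderScan(g$phenotypes[1, ], "seed", 0, seed = 1)
  expect_true(all(pixels(r0$scan) == 0))

  r <- renderScan(g$phenotypes[1, ], "seed", 9, seed = 2)
  expect_identical(r$truth$count, 9L)
  expect_length(r$truth$bboxes, 9L)
  # masks/areas consistent; painted pixels exactly the mask union
  px <- pixels(r$scan)
  lit <- apply(px, c(1, 2), max) > 0
  expect_identical(sum(lit), sum(r$truth$areas))
  for (i in 1:9) {
    b <- r$truth$bboxes[[i]]
    expect_identical(sum(r$truth$masks[[i]]), r$truth$areas[[i]])
    expect_identical(dim(r$truth$masks[[i]]),
                     c(b[3] - b[1], b[4] - b[2]))
  }
  # mean object colour tracks the phenotype hue
  p1 <- g$phenotypes$seedParams[[1]]
  meanRGB <- vapply(1:3, function(ch) mean(px[, , ch][lit]), numeric(1))
  hue <- grDevices::rgb2hsv(meanRGB[1], meanRGB[2], meanRGB[3],
                            maxColorValue = 1)[1, 1]
  dh <- min(abs(hue - p1$hue), 1 - abs(hue - p1$hue))   # circular distance
  expect_lt(dh, 0.08)
  # determinism is byte-exact
  r2 <- renderScan(g$phenotypes[1, ], "seed", 9, seed = 2)
  expect_identical(pixels(r$scan), pixels(r2$scan))
  # capacity error when objects cannot fit
  expect_error(renderScan(g$phenotypes[1, ], "pod", 50,
                          canvas = c(150L, 150L), seed = 3, maxAttempts = 20L),
               "capacity")
})

test_that("dataset generation writes scans, manifest and ground truth", {
  out <- tempfile("synds")
  ds <- generateDataset(K = 4, perClassScans = 2L, objectsPerScan = 5L,
                        outDir = out, seed = 8)
  expect_identical(nrow(ds$scanManifest), 4L * 2L * 2L)
  expect_true(all(file.exists(ds$scanManifest$path)))
  # arithmetic: 4 classes x 2 scans x 5 objects per organ
  perOrgan <- sum(vapply(ds$truth, function(t)
    if (t$organ == "pod") t$count else 0L, integer(1)))
  expect_identical(perOrgan, 40L)
  gt <- jsonlite::read_json(file.path(out, "ground_truth.json"))
  expect_length(gt$scans, 16L)
  expect_identical(unlist(gt$classes), sprintf("L%02d", 1:4))

  # full segmentation round trip recovers every object count
  for (i in seq_len(nrow(ds$scanManifest))) {
    row <- ds$scanManifest[i, ]
    scan <- ScanImage(readImageFile(row$path), row$organ, row$class,
                      row$scan_id)
    expect_length(segmentScan(scan)$objects, 5L)
  }
})

test_that("shrinking the sibling delta does not raise sibling recall", {
  deltas <- c(0.02, 0.08, 0.2)
  recalls <- vapply(deltas, function(d) {
    mean(vapply(1:3, function(s) {
      r <- runSmallPipeline(seed = 400 + s, K = 2, perClassScans = 6,
                            objectsPerScan = 10, nSiblingPairs = 1,
                            siblingDelta = d, analyze = FALSE)
      mean(suppressWarnings(
        precisionRecallF1(r$confusion))@perClass$recall)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(recalls) >= -1e-9))   # monotone up to ties
})
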