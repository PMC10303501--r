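test_that("grayscale conversion applies the luminance weights", {
  black <- array(0, c(4, 5, 3))
  expect_true(all(toGrayscale(black) == 0))
  white <- array(1, c(4, 5, 3))
  expect_equal(toGrayscale(white), matrix(1, 4, 5), tolerance = 1e-12)
  # hand-recomputed weighted sum on known channel values
  withr::with_seed(3, {
    px <- array(runif(6 * 7 * 3), c(6, 7, 3))
  })
  g <- toGrayscale(px)
  expected <- matrix(0, 6, 7)
  for (r in 1:6) for (c in 1:7)
    expected[r, c] <- sum(c(0.299, 0.587, 0.114) * px[r, c, ])
  expect_equal(g, expected, tolerance = 1e-12)
  expect_error(toGrayscale(matrix(0, 3, 3)), "3 channels")
})

test_that("binarization: fixed threshold and Otsu behave as specified", {
  const <- matrix(0.5, 8, 8)
  expect_true(all(objectMask(binarizeImage(const, "fixed", 0.2))))
  expect_error(binarizeImage(const, "fixed"), "threshold")

  # two-level image: Otsu must separate the levels exactly; cross-check
  # against an exhaustive search maximizing between-class variance
  withr::with_seed(11, {
    gray <- matrix(sample(c(40, 200) / 255, 400, replace = TRUE), 20, 20)
  })
  m <- objectMask(binarizeImage(gray, "otsu"))
  expect_identical(m, gray > 100 / 255)
  bcv <- function(th) {
    w0 <- mean(gray <= th); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(0)
    w0 * w1 * (mean(gray[gray > th]) - mean(gray[gray <= th]))^2
  }
  cand <- seq(0, 1, by = 1 / 256)
  best <- cand[which.max(vapply(cand, bcv, numeric(1)))]
  expect_identical(m, gray > best)
})

test_that("fixed-threshold mask recovers the generator's painted pixels", {
  phen <- generatePhenotypes(2, seed = 5)
  r <- renderScan(phen$phenotypes[1, ], "seed", 6, seed = 9)
  gray <- toGrayscale(r$scan)
  m <- objectMask(binarizeImage(gray, "fixed", 0.05))
  expect_identical(sum(m), sum(r$truth$areas))
})

test_that("connected-object extraction: ordering, min area, border drop", {
  expect_identical(extractObjects(matrix(FALSE, 10, 10)), list())

  # two disks plus a 3-pixel speck with minAreaPx = 10 -> 2 ROIs
  m <- matrix(FALSE, 40, 40)
  m[5:12, 5:12] <- TRUE
  m[25:33, 20:28] <- TRUE
  m[38, 35:37] <- TRUE
  rois <- extractObjects(m, minAreaPx = 10L)
  expect_length(rois, 2L)
  expect_identical(bbox(rois[[1]]), c(4L, 4L, 12L, 12L))   # row-major order
  expect_identical(areaPx(rois[[1]]), 64L)
  expect_identical(sum(objectMask(rois[[2]])), areaPx(rois[[2]]))

  # border-touching drop
  m2 <- matrix(FALSE, 20, 20)
  m2[1:4, 5:8] <- TRUE
  m2[10:13, 10:13] <- TRUE
  expect_length(extractObjects(m2, minAreaPx = 1L, dropBorderTouching = TRUE),
                1L)
  # 8- vs 4-connectivity on a diagonal join
  m3 <- matrix(FALSE, 10, 10)
  m3[2:3, 2:3] <- TRUE
  m3[4:5, 4:5] <- TRUE
  expect_length(extractObjects(m3, minAreaPx = 1L, connectivity = 8L), 1L)
  expect_length(extractObjects(m3, minAreaPx = 1L, connectivity = 4L), 2L)
})

test_that("segmentation recovers synthetic scan objects with matching boxes", {
  phen <- generatePhenotypes(3, seed = 21)
  r <- renderScan(phen$phenotypes[2, ], "seed", 12, seed = 22)
  seg <- segmentScan(r$scan)
  expect_length(seg$objects, 12L)
  gray <- toGrayscale(r$scan)
  rois <- extractObjects(binarizeImage(gray, "otsu"))
  gtBoxes <- do.call(rbind, r$truth$bboxes)
  gtBoxes <- gtBoxes[order(gtBoxes[, 1], gtBoxes[, 2]), ]
  segBoxes <- do.call(rbind, lapply(rois, bbox))
  segBoxes <- segBoxes[order(segBoxes[, 1], segBoxes[, 2]), ]
  expect_true(all(abs(gtBoxes - segBoxes) <= 1))
})

test_that("canvas normalization centres the object and zeroes the rest", {
  # 50 x 80 object: black pixel count is exactly 300^2 - mask area
  img <- array(0, c(200, 200, 3))
  img[76:125, 61:140, ] <- 0.8                       # 50 x 80 block
  scan <- ScanImage(img, "pod", "X", "s1")
  roi <- extractObjects(toGrayscale(scan) > 0.1)[[1]]
  out <- normalizeToCanvas(scan, roi)
  expect_identical(dim(pixels(out)), c(300L, 300L, 3L))
  nBlack <- sum(apply(pixels(out), c(1, 2), max) == 0)
  expect_identical(nBlack, 300L * 300L - areaPx(roi))
  expect_identical(sum(objectMask(out)), areaPx(roi))  # area conservation
  # centred: mask centroid at canvas centre within a pixel
  ctr <- colMeans(which(objectMask(out), arr.ind = TRUE))
  expect_true(all(abs(ctr - 150.5) <= 1))

  # object exactly canvas-sized is pasted unscaled
  big <- array(0, c(320, 320, 3))
  big[11:310, 11:310, ] <- 0.6
  scanBig <- ScanImage(big, "pod", "X", "s2")
  roiBig <- extractObjects(toGrayscale(scanBig) > 0.1)[[1]]
  outBig <- normalizeToCanvas(scanBig, roiBig, canvasSize = 300L)
  expect_identical(sum(objectMask(outBig)), 300L * 300L)

  # oversized object: error by default, aspect-preserving rescale on request
  long <- array(0, c(500, 200, 3))
  long[51:450, 81:120, ] <- 0.7                      # 400 x 40 object
  scanLong <- ScanImage(long, "pod", "X", "s3")
  roiLong <- extractObjects(toGrayscale(scanLong) > 0.1)[[1]]
  expect_error(normalizeToCanvas(scanLong, roiLong), "exceeds")
  expect_warning(outL <- normalizeToCanvas(scanLong, roiLong,
                                           overflow = "rescale"),
                 "downscaled")
  expect_identical(dim(pixels(outL)), c(300L, 300L, 3L))
  b <- which(objectMask(outL), arr.ind = TRUE)
  aspect <- (diff(range(b[, 1])) + 1) / (diff(range(b[, 2])) + 1)
  expect_lt(abs(aspect / (400 / 40) - 1), 0.01)
})

test_that("segmentScan composes: empty scans, idempotence, determinism", {
  empty <- ScanImage(array(0, c(120, 120, 3)), "seed", "E", "s0")
  seg0 <- segmentScan(empty)
  expect_length(seg0$objects, 0L)
  expect_identical(nrow(seg0$manifest), 0L)

  phen <- generatePhenotypes(2, seed = 31)
  r <- renderScan(phen$phenotypes[1, ], "pod", 5, seed = 32)
  seg1 <- segmentScan(r$scan)
  expect_length(seg1$objects, 5L)
  expect_identical(seg1$manifest$object_index, 1:5)

  # segmenting a normalized single-object image yields exactly one object
  obj <- seg1$objects[[1]]
  again <- segmentScan(ScanImage(pixels(obj), organ(obj), classLabel(obj),
                                 "re"))
  expect_length(again$objects, 1L)

  # byte-identical determinism
  seg2 <- segmentScan(r$scan)
  expect_identical(lapply(seg1$objects, pixels), lapply(seg2$objects, pixels))
})

test_that("background purity holds across segmented synthetic objects", {
  phen <- generatePhenotypes(2, seed = 41)
  for (org in c("pod", "seed")) {
    r <- renderScan(phen$phenotypes[2, ], org, 4, seed = 43)
    for (obj in segmentScan(r$scan)$objects) {
      outside <- !array(objectMask(obj), dim(pixels(obj)))
      expect_true(all(pixels(obj)[outside] == 0))
    }
  }
})

test_that("binarization and labelling agree with the EBImage reference", {
  phen <- generatePhenotypes(2, seed = 55)
  r <- renderScan(phen$phenotypes[1, ], "pod", 7, seed = 56)
  gray <- toGrayscale(r$scan)
  ours <- objectMask(binarizeImage(gray, "otsu"))
  ref <- gray > EBImage::otsu(EBImage::Image(gray), range = c(0, 1),
                              levels = 256)
  # identical masks (both threshold in the background/object gap)
  expect_identical(unname(ours), unname(ref))
  # component count matches EBImage's labelling
  expect_identical(length(extractObjects(ours, minAreaPx = 1L)),
                   as.integer(max(EBImage::bwlabel(ours))))
})
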