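## Segmentation: scanner image -> grayscale -> binary mask -> connected
## objects -> centred 300x300 black-canvas single-object images.

#' Convert an RGB scan to grayscale
#'
#' Luminance-weighted channel combination (ITU-R BT.601 weights
#' 0.299 R + 0.587 G + 0.114 B), the classical grayscale conversion.
#'
#' @param image A [ScanImage-class] or an `H x W x 3` array in `[0, 1]`.
#' @return Numeric `H x W` matrix in `[0, 1]`.
#' @export
toGrayscale <- function(image) {
  p <- if (is(image, "ScanImage")) pixels(image) else image
  if (length(dim(p)) != 3L || dim(p)[3L] != 3L)
    stopf("toGrayscale: input must have exactly 3 channels")
  0.299 * p[, , 1L] + 0.587 * p[, , 2L] + 0.114 * p[, , 3L]
}

# Otsu threshold on a [0,1] grayscale matrix: maximize between-class variance
# over a 256-bin histogram; returns the threshold on the [0,1] scale.
# Foreground is gray > threshold.
otsuThreshold <- function(gray, nbins = 256L) {
  h <- tabulate(pmin(as.integer(gray * nbins) + 1L, nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nbins) - 1L))
  muT <- mu[nbins]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  k <- which.max(sigmaB)          # first bin maximizing between-class variance
  k / nbins                       # upper edge of bin k on [0,1]
}

#' Binarize a grayscale image
#'
#' @param gray Numeric matrix in `[0, 1]`.
#' @param method `"otsu"` (between-class variance maximization over a 256-bin
#'   histogram) or `"fixed"`.
#' @param threshold Threshold in `[0, 1]` (required for `method = "fixed"`).
#'   Foreground is `gray > threshold`.
#' @return A [BinaryMask-class].
#' @export
binarizeImage <- function(gray, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(gray)) stopf("binarizeImage: gray must be a matrix")
  th <- switch(method,
    fixed = {
      if (is.null(threshold))
        stopf("binarizeImage: method 'fixed' requires a threshold")
      threshold
    },
    otsu = otsuThreshold(gray))
  new("BinaryMask", mask = gray > th)
}

#' Extract connected objects from a binary mask
#'
#' One [ObjectROI-class] per connected foreground component with area at
#' least `minAreaPx`. Ordering is deterministic: row-major by bounding-box
#' top-left corner (ties broken by column, then by label).
#'
#' @param mask A [BinaryMask-class] or logical matrix.
#' @param minAreaPx Minimum component area in pixels.
#' @param connectivity 4 or 8 (default) neighbour connectivity.
#' @param dropBorderTouching Drop components touching the image border.
#' @return List of [ObjectROI-class] (possibly empty).
#' @export
extractObjects <- function(mask, minAreaPx = 64L, connectivity = 8L,
                           dropBorderTouching = FALSE) {
  m <- if (is(mask, "BinaryMask")) objectMask(mask) else mask
  if (!is.logical(m)) stopf("extractObjects: mask must be logical")
  if (!connectivity %in% c(4L, 8L))
    stopf("extractObjects: connectivity must be 4 or 8")
  if (!any(m)) return(list())
  lab <- label_components_cpp(m, as.integer(connectivity))
  H <- nrow(m); W <- ncol(m)
  ids <- seq_len(max(lab))
  rois <- list()
  meta <- matrix(NA_integer_, nrow = 0L, ncol = 2L)
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < minAreaPx) next
    r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
    c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
    if (dropBorderTouching && (r0 == 1L || c0 == 1L || r1 == H || c1 == W))
      next
    crop <- lab[r0:r1, c0:c1, drop = FALSE] == id
    roi <- new("ObjectROI",
               bbox = as.integer(c(r0 - 1L, c0 - 1L, r1, c1)),
               areaPx = nrow(idx), maskCrop = crop)
    rois[[length(rois) + 1L]] <- roi
    meta <- rbind(meta, c(r0, c0))
  }
  if (length(rois) == 0L) return(list())
  rois[order(meta[, 1L], meta[, 2L])]
}

#' Paste one segmented object centred on a square black canvas
#'
#' Object pixels are copied from the source image under the ROI mask; every
#' other canvas pixel is exactly (0,0,0), so true object size is preserved.
#' Objects larger than the canvas either raise an error or are downscaled
#' aspect-preserving (with a warning), per `overflow`.
#'
#' @param image [ScanImage-class] (or `H x W x 3` array) the ROI refers to.
#' @param roi An [ObjectROI-class].
#' @param canvasSize Canvas side length in pixels (default 300).
#' @param overflow `"error"` or `"rescale"`.
#' @param objectIndex Index recorded in the output.
#' @return A [NormalizedObjectImage-class].
#' @export
normalizeToCanvas <- function(image, roi, canvasSize = 300L,
                              overflow = c("error", "rescale"),
                              objectIndex = 1L) {
  overflow <- match.arg(overflow)
  isScan <- is(image, "ScanImage")
  p <- if (isScan) pixels(image) else image
  b <- bbox(roi)
  if (b[1L] < 0L || b[2L] < 0L || b[3L] > dim(p)[1L] || b[4L] > dim(p)[2L])
    stopf("normalizeToCanvas: ROI outside image bounds")
  crop <- p[(b[1L] + 1L):b[3L], (b[2L] + 1L):b[4L], , drop = FALSE]
  m <- objectMask(roi)
  crop <- crop * array(m, dim(crop))    # zero out background within the box
  h <- nrow(m); w <- ncol(m)
  if (h > canvasSize || w > canvasSize) {
    if (overflow == "error")
      stopf("normalizeToCanvas: object %d x %d exceeds canvas %d", h, w,
            canvasSize)
    s <- canvasSize / max(h, w)
    nh <- max(1L, as.integer(floor(h * s)))
    nw <- max(1L, as.integer(floor(w * s)))
    warning(sprintf(
      "normalizeToCanvas: object %d x %d downscaled to %d x %d", h, w, nh, nw))
    crop <- resizeBilinear(crop, nh, nw)
    m <- resizeBilinear(m * 1, nh, nw) >= 0.5
    crop <- crop * array(m, dim(crop))
    h <- nh; w <- nw
  }
  canvas <- array(0, c(canvasSize, canvasSize, 3L))
  cmask <- matrix(FALSE, canvasSize, canvasSize)
  r0 <- as.integer(floor((canvasSize - h) / 2))    # centred placement
  c0 <- as.integer(floor((canvasSize - w) / 2))
  canvas[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w), ] <- crop
  cmask[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w)] <- m
  new("NormalizedObjectImage", pixels = canvas, mask = cmask,
      sourceScan = if (isScan) scanId(image) else "array",
      objectIndex = as.integer(objectIndex),
      organ = if (isScan) organ(image) else "seed",
      classLabel = if (isScan) classLabel(image) else "unknown")
}

#' Segment a scan into normalized single-object images
#'
#' Composition of [toGrayscale()], [binarizeImage()], [extractObjects()] and
#' [normalizeToCanvas()]. Optionally writes one PNG per object (named
#' `{class}_{organ}_{scanId}_{idx}.png`) and returns manifest rows.
#'
#' @param image A [ScanImage-class].
#' @param minAreaPx,connectivity,dropBorderTouching See [extractObjects()].
#' @param method,threshold See [binarizeImage()].
#' @param canvasSize,overflow See [normalizeToCanvas()].
#' @param outDir Output directory for PNGs, or `NULL` to keep in memory only.
#' @return List with `objects` (list of [NormalizedObjectImage-class]) and
#'   `manifest` (data.frame with columns path, class, organ, scan_id,
#'   object_index, area_px, split).
#' @export
segmentScan <- function(image, minAreaPx = 64L, connectivity = 8L,
                        dropBorderTouching = FALSE, method = "otsu",
                        threshold = NULL, canvasSize = 300L,
                        overflow = "error", outDir = NULL) {
  stopifnot(is(image, "ScanImage"))
  gray <- toGrayscale(image)
  mask <- binarizeImage(gray, method = method, threshold = threshold)
  rois <- extractObjects(mask, minAreaPx = minAreaPx,
                         connectivity = connectivity,
                         dropBorderTouching = dropBorderTouching)
  objects <- vector("list", length(rois))
  rows <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    obj <- normalizeToCanvas(image, rois[[i]], canvasSize = canvasSize,
                             overflow = overflow, objectIndex = i)
    path <- NA_character_
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      path <- file.path(outDir, sprintf("%s_%s_%s_%03d.png",
                                        classLabel(image), organ(image),
                                        scanId(image), i))
      writeImageFile(pixels(obj), path)
    }
    objects[[i]] <- obj
    rows[[i]] <- data.frame(
      path = path, class = classLabel(image), organ = organ(image),
      scan_id = scanId(image), object_index = i,
      area_px = areaPx(rois[[i]]), split = "unassigned",
      stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else emptyManifest()
  list(objects = objects, manifest = manifest)
}

emptyManifest <- function() {
  data.frame(path = character(), class = character(), organ = character(),
             scan_id = character(), object_index = integer(),
             area_px = integer(), split = character(),
             stringsAsFactors = FALSE)
}
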