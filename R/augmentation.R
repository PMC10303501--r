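## Augmentation and dataset bookkeeping: geometric transforms on the black
## canvas, class balancing to a target count, and stratified 8:1:1 splits.

rot90cw <- function(m) t(m[nrow(m):1L, , drop = FALSE])

rotateExact <- function(a, quarters) {
  for (i in seq_len(quarters %% 4L)) {
    if (length(dim(a)) == 3L) {
      a <- array(apply(a, 3L, rot90cw), c(dim(a)[2L], dim(a)[1L], dim(a)[3L]))
    } else a <- rot90cw(a)
  }
  a
}

rotateNearest <- function(a, angleDeg) {
  isMat <- is.matrix(a)
  if (isMat) a <- array(a, c(dim(a), 1L))
  d <- dim(a)
  th <- angleDeg * pi / 180
  ctr <- (d[1:2] + 1) / 2
  g <- expand.grid(r = seq_len(d[1L]), c = seq_len(d[2L]))
  dr <- g$r - ctr[1L]; dc <- g$c - ctr[2L]
  sr <- round(cos(th) * dr - sin(th) * dc + ctr[1L])   # inverse rotation
  sc <- round(sin(th) * dr + cos(th) * dc + ctr[2L])
  ok <- sr >= 1 & sr <= d[1L] & sc >= 1 & sc <= d[2L]
  out <- array(0, d)
  for (ch in seq_len(d[3L])) {
    plane <- matrix(0, d[1L], d[2L])
    plane[cbind(g$r[ok], g$c[ok])] <- a[cbind(sr[ok], sc[ok], ch)]
    out[, , ch] <- plane
  }
  if (isMat) out[, , 1L] else out
}

shiftArray <- function(a, dr, dc) {
  isMat <- is.matrix(a)
  if (isMat) a <- array(a, c(dim(a), 1L))
  d <- dim(a)
  out <- array(0, d)
  srcR <- seq_len(d[1L]) - dr; srcC <- seq_len(d[2L]) - dc
  okR <- srcR >= 1 & srcR <= d[1L]; okC <- srcC >= 1 & srcC <= d[2L]
  out[okR, okC, ] <- a[srcR[okR], srcC[okC], , drop = FALSE]
  if (isMat) out[, , 1L] else out
}

maskBBox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(min(idx[, 1L]), min(idx[, 2L]), max(idx[, 1L]), max(idx[, 2L]))
}

# Apply one sampled policy op to (pixels, mask); shifts are capped so the
# object's bounding box never leaves the canvas (background stays black).
applyRandomOp <- function(px, mask, policy) {
  op <- policy@ops[sample.int(length(policy@ops), 1L)]
  S <- nrow(mask)
  switch(op,
    rotate = {
      ang <- policy@rotateAngles[sample.int(length(policy@rotateAngles), 1L)]
      if (ang %% 90 == 0) {
        q <- (ang %/% 90) %% 4
        list(pixels = rotateExact(px, q), mask = rotateExact(mask, q))
      } else {
        m2 <- rotateNearest(mask * 1, ang) > 0.5
        p2 <- rotateNearest(px, ang) * array(m2, dim(px))
        list(pixels = p2, mask = m2)
      }
    },
    shift = {
      b <- maskBBox(mask)
      cap <- floor(policy@shiftMaxFraction * S)
      drRange <- c(-min(cap, b[1L] - 1L), min(cap, S - b[3L]))
      dcRange <- c(-min(cap, b[2L] - 1L), min(cap, S - b[4L]))
      dr <- if (drRange[1L] < drRange[2L])
        sample(drRange[1L]:drRange[2L], 1L) else 0L
      dc <- if (dcRange[1L] < dcRange[2L])
        sample(dcRange[1L]:dcRange[2L], 1L) else 0L
      list(pixels = shiftArray(px, dr, dc), mask = shiftArray(mask * 1, dr, dc) > 0.5)
    },
    flip_vertical = list(pixels = px[nrow(px):1L, , , drop = FALSE],
                         mask = mask[nrow(mask):1L, , drop = FALSE]),
    mirror_horizontal = list(pixels = px[, ncol(px):1L, , drop = FALSE],
                             mask = mask[, ncol(mask):1L, drop = FALSE]))
}

#' Balance one (class, organ) group to a target count
#'
#' Keeps all originals and appends seeded random augmentations (source image,
#' operation and its parameter each drawn uniformly) until `targetCount`
#' images exist. Shifted content never leaves the canvas; output order is
#' deterministic given the policy seed.
#'
#' @param images Non-empty list of [NormalizedObjectImage-class].
#' @param targetCount Desired group size (`>= length(images)`).
#' @param policy An [AugmentationPolicy-class].
#' @return List of `targetCount` [NormalizedObjectImage-class] objects
#'   (originals first).
#' @export
augmentGroup <- function(images, targetCount, policy = augmentationPolicy()) {
  if (length(images) == 0L) stopf("augmentGroup: empty input group")
  if (targetCount < length(images))
    stopf("augmentGroup: targetCount (%d) below group size (%d)",
          targetCount, length(images))
  n <- length(images)
  extra <- targetCount - n
  out <- images
  withSeed(policy@seed, {
    for (i in seq_len(extra)) {
      src <- images[[sample.int(n, 1L)]]
      tr <- applyRandomOp(src@pixels, src@mask, policy)
      out[[n + i]] <- new("NormalizedObjectImage", pixels = tr$pixels,
                          mask = tr$mask, sourceScan = src@sourceScan,
                          objectIndex = src@objectIndex, organ = src@organ,
                          classLabel = src@classLabel)
    }
  })
  out
}

#' Read / write a dataset manifest CSV
#'
#' The manifest schema is `path, class, organ, scan_id, object_index,
#' area_px, split` plus, after augmentation, `is_augmented` and
#' `source_path`.
#'
#' @param path CSV path.
#' @return `readManifest` returns the manifest data.frame.
#' @export
readManifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "class", "organ", "scan_id", "object_index", "area_px",
            "split")
  if (!all(need %in% names(m)))
    stopf("manifest missing columns: %s",
          paste(setdiff(need, names(m)), collapse = ", "))
  m$class <- as.character(m$class)
  m
}

#' @rdname readManifest
#' @param manifest Manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Splits each (class, organ) group independently with a seeded shuffle.
#' Allocation is floor-based on the `ratios` shares for validation and test,
#' with the remainder going to train: 1000 rows at 8:1:1 give exactly
#' 800/100/100, 1001 rows give 801/100/100.
#'
#' @param manifest Manifest data.frame.
#' @param ratios Length-3 positive weights for train/val/test.
#' @param seed RNG seed.
#' @return The manifest with `split` assigned (`train`/`val`/`test`).
#' @export
splitManifest <- function(manifest, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  groups <- split(seq_len(nrow(manifest)),
                  paste(manifest$class, manifest$organ, sep = "\r"))
  groups <- groups[order(names(groups))]
  total <- sum(ratios)
  withSeed(seed, {
    for (idx in groups) {
      n <- length(idx)
      if (n < 3L) stopf("splitManifest: group smaller than 3 (%d rows)", n)
      nVal <- floor(n * ratios[2L] / total)
      nTest <- floor(n * ratios[3L] / total)
      nTrain <- n - nVal - nTest
      perm <- idx[sample.int(n)]
      manifest$split[perm[seq_len(nTrain)]] <- "train"
      manifest$split[perm[nTrain + seq_len(nVal)]] <- "val"
      manifest$split[perm[nTrain + nVal + seq_len(nTest)]] <- "test"
    }
  })
  manifest
}

#' Balance all groups on disk and split the manifest
#'
#' Disk-based composition of [augmentGroup()] and [splitManifest()] that
#' never holds more than one image in memory. Two modes:
#' \describe{
#'   \item{`split_before_augment` (default)}{Originals are split first; only
#'     the training partition is augmented, to the training share of
#'     `targetPerGroup` (800 for a target of 1000 at 8:1:1). An augmented
#'     image can therefore never share information with validation or test.}
#'   \item{`augment_then_split`}{Each group is augmented to `targetPerGroup`
#'     first and the full group (originals plus augmentations) is then split
#'     8:1:1, reproducing the classical augment-then-split order.}
#' }
#' Augmented files are written beside their source with suffix `_augNNN`.
#'
#' @param manifest Manifest of original (non-augmented) rows whose `path`
#'   column points at readable images.
#' @param targetPerGroup Target image count per (class, organ) group.
#' @param policy An [AugmentationPolicy-class]; its seed drives the sampling.
#' @param mode `"split_before_augment"` or `"augment_then_split"`.
#' @param ratios,seed Passed to [splitManifest()].
#' @return The augmented, split manifest (columns `is_augmented`,
#'   `source_path` added).
#' @export
augmentManifest <- function(manifest, targetPerGroup = 1000L,
                            policy = augmentationPolicy(),
                            mode = c("split_before_augment", "augment_then_split"),
                            ratios = c(8, 1, 1), seed = 1L) {
  mode <- match.arg(mode)
  manifest$is_augmented <- FALSE
  manifest$source_path <- NA_character_
  if (mode == "augment_then_split") {
    aug <- augmentGroupsOnDisk(manifest, targetPerGroup, policy)
    splitManifest(aug, ratios = ratios, seed = seed)
  } else {
    manifest <- splitManifest(manifest, ratios = ratios, seed = seed)
    trainTarget <- as.integer(floor(targetPerGroup * ratios[1L] / sum(ratios)))
    train <- manifest[manifest$split == "train", , drop = FALSE]
    rest <- manifest[manifest$split != "train", , drop = FALSE]
    aug <- augmentGroupsOnDisk(train, trainTarget, policy, split = "train")
    rbind(aug, rest)
  }
}

augmentGroupsOnDisk <- function(manifest, target, policy, split = NULL) {
  keys <- sort(unique(paste(manifest$class, manifest$organ, sep = "\r")))
  out <- list(manifest)
  for (g in seq_along(keys)) {
    parts <- strsplit(keys[g], "\r", fixed = TRUE)[[1L]]
    rows <- manifest[manifest$class == parts[1L] & manifest$organ == parts[2L],
                     , drop = FALSE]
    n <- nrow(rows)
    if (n == 0L) stopf("augmentManifest: empty group %s/%s", parts[1L], parts[2L])
    if (target < n)
      stopf("augmentManifest: target (%d) below group size (%d)", target, n)
    extra <- target - n
    if (extra == 0L) next
    newRows <- rows[rep(1L, extra), , drop = FALSE]
    withSeed(childSeed(policy@seed, g), {
      for (i in seq_len(extra)) {
        src <- rows[sample.int(n, 1L), ]
        px <- readImageFile(src$path)
        mask <- apply(px, c(1L, 2L), max) > 0
        tr <- applyRandomOp(px, mask, policy)
        path <- sub("\\.png$", sprintf("_aug%03d.png", i), src$path)
        writeImageFile(tr$pixels, path)
        newRows[i, ] <- src
        newRows$path[i] <- path
        newRows$is_augmented[i] <- TRUE
        newRows$source_path[i] <- src$path
        if (!is.null(split)) newRows$split[i] <- split
      }
    })
    out[[length(out) + 1L]] <- newRows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (anyDuplicated(res$path)) stopf("augmentManifest: duplicate paths produced")
  res
}
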