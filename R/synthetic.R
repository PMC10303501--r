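## Synthetic paired pod/seed scan generator with exact ground truth.
##
## Classes are parametric phenotypes: seeds are speckled ellipses with a
## hilum patch, pods are curved chains of 2-4 lobes with a longitudinal
## texture. A designated partner structure controls difficulty: sibling
## pairs differ by a small multiplicative delta in both organs (emulating
## near-indistinguishable mutant line pairs), complementary pairs are
## IDENTICAL in one organ's parameters and distinguishable only via the
## other organ (the signal that makes organ fusion pay off), and the
## remaining classes differ in both organs. Objects are placed without
## touching (padded-bounding-box rejection sampling), mirroring scans from
## which adhered objects were removed.

hsv2rgbVec <- function(h, s, v) {
  as.numeric(col2rgb(grDevices::hsv(h %% 1, s, v))) / 255
}

# Saturation/value ranges keep objects bright against the black scanner
# background (as in real scans with the cover open), so that histogram
# thresholding always finds the background/object gap rather than a split
# inside a dark object.
sampleSeedParams <- function(hue) {
  list(axisA = runif(1, 16, 24), axisB = runif(1, 11, 17),
       rgb = hsv2rgbVec(hue, runif(1, 0.4, 0.75), runif(1, 0.6, 0.95)),
       hue = hue %% 1,
       speckle = runif(1, 0.002, 0.012), hilum = runif(1, 0.3, 0.7))
}

samplePodParams <- function(hue) {
  list(len = runif(1, 40, 60), width = runif(1, 10, 16),
       curvature = runif(1, 0.1, 0.4), lobes = sample(2:4, 1),
       rgb = hsv2rgbVec(hue, runif(1, 0.4, 0.75), runif(1, 0.55, 0.9)),
       hue = hue %% 1, texFreq = runif(1, 2, 6))
}

# Siblings share colour and differ only by a small size delta, the typical
# near-indistinguishable pair: a systematic shape offset hidden inside the
# per-object pose/size jitter.
perturbSeed <- function(p, delta) {
  p$axisA <- p$axisA * (1 + delta); p$axisB <- p$axisB * (1 + delta)
  p
}

perturbPod <- function(p, delta) {
  p$len <- p$len * (1 + delta); p$width <- p$width * (1 + delta)
  p
}

#' Generate class phenotypes with sibling and complementary structure
#'
#' Classes are organized in partner pairs `(1,2), (3,4), ...`. The first
#' `nSiblingPairs` pairs are siblings: the partner's parameters are the
#' class's parameters scaled by `1 + siblingDelta` in both organs, yielding
#' near-duplicate classes. Of the remaining pairs, a fraction
#' `complementarity` is complementary: the partners share IDENTICAL
#' parameters in one organ (alternating pod/seed) and differ clearly in the
#' other, so only one organ carries the discriminative signal. All other
#' classes differ in both organs (distinct hues spaced on the colour wheel).
#'
#' @param K Number of classes (>= 2).
#' @param nSiblingPairs Number of sibling pairs (`2 * nSiblingPairs <= K`).
#' @param complementarity Fraction of remaining partner pairs that are
#'   one-organ-distinguishable, in `[0, 1]`.
#' @param seed RNG seed.
#' @param siblingDelta Relative parameter offset between siblings.
#' @return List with `phenotypes` (one-row-per-class data.frame with nested
#'   `seedParams`/`podParams` list-columns, `role`, `partner`,
#'   `informativeOrgan`), `siblings` (data.frame of sibling pairs), and the
#'   generator `seed` — the dataset-level ground-truth header.
#' @export
generatePhenotypes <- function(K, nSiblingPairs = 0L, complementarity = 0,
                               seed = 1L, siblingDelta = 0.015) {
  if (K < 2L) stopf("K must be >= 2")
  if (2L * nSiblingPairs > K)
    stopf("2 * nSiblingPairs must be <= K")
  nPairs <- K %/% 2L
  if (nSiblingPairs > nPairs) stopf("not enough classes for sibling pairs")
  withSeed(seed, {
    classes <- sprintf("L%02d", seq_len(K))
    # well-spread hues; partner pairs get far-apart base hues so that
    # 'distinct' classes never collide in colour
    hues <- (seq_len(K) - 1) / K + runif(1) # global rotation
    seedP <- lapply(hues, sampleSeedParams)
    podP <- lapply(hues + 0.33, samplePodParams)
    role <- rep("distinct", K)
    partner <- rep(NA_character_, K)
    informative <- rep("both", K)
    restPairs <- if (nSiblingPairs < nPairs)
      (nSiblingPairs + 1L):nPairs else integer()
    nComp <- round(complementarity * length(restPairs))
    compPairs <- head(restPairs, nComp)
    for (p in seq_len(nPairs)) {
      a <- 2L * p - 1L; b <- 2L * p
      partner[a] <- classes[b]; partner[b] <- classes[a]
      if (p <= nSiblingPairs) {
        role[c(a, b)] <- "sibling"
        seedP[[b]] <- perturbSeed(seedP[[a]], siblingDelta)
        podP[[b]] <- perturbPod(podP[[a]], siblingDelta)
        informative[c(a, b)] <- "both"
      } else if (p %in% compPairs) {
        role[c(a, b)] <- "complementary"
        org <- if ((match(p, compPairs) %% 2L) == 1L) "pod" else "seed"
        informative[c(a, b)] <- org
        if (org == "pod") seedP[[b]] <- seedP[[a]]  # seeds identical
        else podP[[b]] <- podP[[a]]                 # pods identical
      }
    }
    phen <- data.frame(class = classes, role = role, partner = partner,
                       informativeOrgan = informative,
                       stringsAsFactors = FALSE)
    phen$seedParams <- seedP
    phen$podParams <- podP
    sib <- phen[phen$role == "sibling", ]
    siblings <- if (nrow(sib))
      unique(data.frame(classA = pmin(sib$class, sib$partner),
                        classB = pmax(sib$class, sib$partner),
                        stringsAsFactors = FALSE))
    else data.frame(classA = character(), classB = character())
    list(phenotypes = phen, siblings = siblings, seed = as.integer(seed))
  })
}

# Render one object patch (local grid); returns list(rgbPatch, mask).
renderObjectPatch <- function(params, organ, sizeJitter = 1, theta = 0) {
  if (organ == "seed") {
    a <- params$axisA * sizeJitter; b <- params$axisB * sizeJitter
    R <- ceiling(max(a, b)) + 2L
    n <- 2L * R + 1L
    gx <- matrix(rep(seq(-R, R), each = n), n)        # columns
    gy <- matrix(rep(seq(-R, R), times = n), n)       # rows
    u <- cos(theta) * gx + sin(theta) * gy
    v <- -sin(theta) * gx + cos(theta) * gy
    mask <- (u / a)^2 + (v / b)^2 <= 1
    shade <- 1 + 0.06 * (u / a)                        # mild lighting gradient
    col <- array(0, c(n, n, 3L))
    for (ch in 1:3) col[, , ch] <- params$rgb[ch] * shade
    # hilum: darker patch near one end of the major axis
    hil <- ((u - 0.55 * a) / (0.3 * a))^2 + (v / (0.35 * b))^2 <= 1
    for (ch in 1:3)
      col[, , ch][hil] <- col[, , ch][hil] * (1 - 0.6 * params$hilum)
    # speckles
    nSpeck <- round(params$speckle * sum(mask))
    if (nSpeck > 0) {
      idx <- which(mask)
      pts <- idx[sample.int(length(idx), min(nSpeck, length(idx)))]
      for (ch in 1:3) {
        plane <- col[, , ch]
        plane[pts] <- plane[pts] * 0.55
        col[, , ch] <- plane
      }
    }
  } else {
    len <- params$len * sizeJitter; wid <- params$width * sizeJitter
    R <- ceiling(len + wid + abs(params$curvature) * len) + 2L
    n <- 2L * R + 1L
    gx <- matrix(rep(seq(-R, R), each = n), n)
    gy <- matrix(rep(seq(-R, R), times = n), n)
    u <- cos(theta) * gx + sin(theta) * gy
    v <- -sin(theta) * gx + cos(theta) * gy
    mask <- matrix(FALSE, n, n)
    lobes <- params$lobes
    ts <- seq(-1, 1, length.out = lobes)
    la <- 1.25 * len / lobes                           # lobe half-length
    for (t in ts) {
      cx <- t * (len - la)
      cy <- params$curvature * len * (t^2 - 0.5)
      mask <- mask | (((u - cx) / la)^2 + ((v - cy) / wid)^2 <= 1)
    }
    # connecting spine along the curved axis keeps the pod one component
    # even for narrow, strongly curved, many-lobed shapes
    tu <- u / (len - la)
    spine <- abs(tu) <= 1 &
      abs(v - params$curvature * len * (tu^2 - 0.5)) <= 0.7 * wid
    mask <- mask | spine
    tex <- 1 + 0.12 * sin(params$texFreq * pi * u / len)
    col <- array(0, c(n, n, 3L))
    for (ch in 1:3) col[, , ch] <- params$rgb[ch] * tex
  }
  for (ch in 1:3) {
    plane <- col[, , ch]
    plane[!mask] <- 0
    col[, , ch] <- clamp01(plane)
  }
  # keep foreground visibly above black so thresholding cannot lose pixels
  lum <- 0.299 * col[, , 1] + 0.587 * col[, , 2] + 0.114 * col[, , 3]
  low <- mask & lum < 0.2
  if (any(low)) for (ch in 1:3) {
    plane <- col[, , ch]
    plane[low] <- pmax(plane[low], 0.2)
    col[, , ch] <- plane
  }
  list(rgb = col, mask = mask)
}

#' Render a synthetic multi-object scan
#'
#' Draws `nObjects` non-touching objects of one class and organ, with
#' per-object pose jitter (rotation, ~5% size), on a black canvas. Object
#' placement uses rejection sampling on gap-padded tight bounding boxes; if
#' a placement cannot be found within the attempt cap a capacity error is
#' raised. Exact per-object masks and boxes are returned as ground truth.
#'
#' @param phenotype One row of the phenotype table (see
#'   [generatePhenotypes()]).
#' @param organ `"pod"` or `"seed"`.
#' @param nObjects Number of objects (0 gives a pure black scan).
#' @param canvas `(H, W)` canvas size in pixels.
#' @param seed RNG seed.
#' @param gap Minimum pixel gap between object bounding boxes.
#' @param maxAttempts Placement attempts per object before failing.
#' @param scanId Scan identifier.
#' @return List with `scan` (a [ScanImage-class]) and `truth` (object
#'   count, 0-based half-open bboxes, mask crops, areas, class label).
#' @export
renderScan <- function(phenotype, organ, nObjects, canvas = c(600L, 600L),
                       seed = 1L, gap = 3L, maxAttempts = 200L,
                       scanId = "scan") {
  params <- if (organ == "seed") phenotype$seedParams[[1L]]
            else phenotype$podParams[[1L]]
  H <- canvas[1L]; W <- canvas[2L]
  img <- array(0, c(H, W, 3L))
  boxes <- matrix(0L, 0L, 4L)
  truth <- list()
  withSeed(seed, {
    for (i in seq_len(nObjects)) {
      placed <- FALSE
      for (attempt in seq_len(maxAttempts)) {
        patch <- renderObjectPatch(params, organ,
                                   sizeJitter = exp(rnorm(1, 0, 0.05)),
                                   theta = runif(1, 0, 2 * pi))
        pb <- maskBBox(patch$mask)
        ph <- pb[3L] - pb[1L] + 1L; pw <- pb[4L] - pb[2L] + 1L
        if (ph + 2L > H || pw + 2L > W) next
        r0 <- sample.int(H - ph + 1L, 1L)
        c0 <- sample.int(W - pw + 1L, 1L)
        cand <- c(r0, c0, r0 + ph - 1L, c0 + pw - 1L)
        ok <- TRUE
        if (nrow(boxes) > 0L) {
          sep <- cand[3L] + gap < boxes[, 1L] | boxes[, 3L] + gap < cand[1L] |
                 cand[4L] + gap < boxes[, 2L] | boxes[, 4L] + gap < cand[2L]
          ok <- all(sep)
        }
        if (!ok) next
        m <- patch$mask[pb[1L]:pb[3L], pb[2L]:pb[4L], drop = FALSE]
        rgbCrop <- patch$rgb[pb[1L]:pb[3L], pb[2L]:pb[4L], , drop = FALSE]
        rows <- r0:(r0 + ph - 1L); cols <- c0:(c0 + pw - 1L)
        sub <- img[rows, cols, , drop = FALSE]
        sel <- array(m, dim(sub))
        sub[sel] <- rgbCrop[sel]
        img[rows, cols, ] <- sub
        boxes <- rbind(boxes, cand)
        truth[[i]] <- list(
          bbox = as.integer(c(r0 - 1L, c0 - 1L, r0 + ph - 1L, c0 + pw - 1L)),
          area = sum(m), mask = m)
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("renderScan: could not place object %d of %d (capacity)", i,
              nObjects)
    }
  })
  scan <- ScanImage(img, organ = organ, classLabel = phenotype$class,
                    scanId = scanId)
  list(scan = scan,
       truth = list(count = as.integer(nObjects),
                    bboxes = lapply(truth, `[[`, "bbox"),
                    areas = vapply(truth, `[[`, integer(1L), "area"),
                    masks = lapply(truth, `[[`, "mask"),
                    class = phenotype$class, organ = organ,
                    scanId = scanId))
}

#' Generate a full paired-organ synthetic dataset
#'
#' Renders `perClassScans` scans per class per organ, writes scan PNGs and a
#' ground-truth JSON under `outDir`, and returns the scan manifest plus full
#' ground truth (including per-object masks, kept in memory only).
#'
#' @param K Number of classes, or pass a prebuilt `phenotypes` object.
#' @param perClassScans Scans per (class, organ).
#' @param objectsPerScan Objects per scan.
#' @param outDir Output directory (created); `NULL` keeps scans in memory.
#' @param seed RNG seed.
#' @param phenotypes Optional result of [generatePhenotypes()].
#' @param nSiblingPairs,complementarity,siblingDelta Passed to
#'   [generatePhenotypes()] when `phenotypes` is not supplied.
#' @param canvas Scan canvas `(H, W)`.
#' @param organs Organs to render.
#' @return List with `scans` (list of [ScanImage-class], when
#'   `outDir = NULL`), `scanManifest` (path/class/organ/scan_id), `truth`
#'   (per-scan ground truth), and `phenotypes`.
#' @export
generateDataset <- function(K, perClassScans = 4L, objectsPerScan = 10L,
                            outDir = NULL, seed = 1L, phenotypes = NULL,
                            nSiblingPairs = 0L, complementarity = 0,
                            siblingDelta = 0.015, canvas = c(600L, 600L),
                            organs = c("pod", "seed")) {
  if (is.null(phenotypes))
    phenotypes <- generatePhenotypes(K, nSiblingPairs = nSiblingPairs,
                                     complementarity = complementarity,
                                     seed = seed,
                                     siblingDelta = siblingDelta)
  phen <- phenotypes$phenotypes
  if (!is.null(outDir))
    dir.create(file.path(outDir, "scans"), recursive = TRUE,
               showWarnings = FALSE)
  rows <- list(); truths <- list(); scans <- list()
  k <- 0L
  for (ci in seq_len(nrow(phen))) {
    for (org in organs) {
      for (s in seq_len(perClassScans)) {
        k <- k + 1L
        sid <- sprintf("%s_%s_s%02d", phen$class[ci], org, s)
        r <- renderScan(phen[ci, ], org, objectsPerScan, canvas = canvas,
                        seed = childSeed(seed, k), scanId = sid)
        path <- NA_character_
        if (!is.null(outDir)) {
          path <- file.path(outDir, "scans", paste0(sid, ".png"))
          writeImageFile(pixels(r$scan), path)
        } else scans[[sid]] <- r$scan
        truths[[sid]] <- r$truth
        rows[[k]] <- data.frame(path = path, class = phen$class[ci],
                                organ = org, scan_id = sid,
                                stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    gt <- list(seed = phenotypes$seed,
               siblings = phenotypes$siblings,
               classes = phen$class,
               scans = lapply(truths, function(t)
                 t[c("count", "bboxes", "areas", "class", "organ", "scanId")]))
    jsonlite::write_json(gt, file.path(outDir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(scans = if (is.null(outDir)) scans else NULL,
       scanManifest = manifest, truth = truths, phenotypes = phenotypes)
}
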