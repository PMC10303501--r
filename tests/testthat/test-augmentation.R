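test_that("augmentGroup balances to the target with seeded transforms", {
  imgs <- separableImageSet(nPerClass = 5L)[1:5]
  out <- augmentGroup(imgs, 23L, augmentationPolicy(seed = 9))
  expect_length(out, 23L)
  expect_identical(out[1:5], imgs)                       # originals kept
  # background stays exactly black on every augmented image
  for (im in out[6:23]) {
    outside <- !array(objectMask(im), dim(pixels(im)))
    expect_true(all(pixels(im)[outside] == 0))
  }
  # deterministic given the seed
  out2 <- augmentGroup(imgs, 23L, augmentationPolicy(seed = 9))
  expect_identical(lapply(out, pixels), lapply(out2, pixels))
  # no-op when target equals input size
  expect_identical(augmentGroup(imgs, 5L), imgs)
  # errors
  expect_error(augmentGroup(list(), 5L), "empty")
  expect_error(augmentGroup(imgs, 3L), "below")
})

test_that("flip and mirror are involutions", {
  im <- diskImage(seed = 5)
  flip <- function(p) p[nrow(p):1, , , drop = FALSE]
  mirror <- function(p) p[, ncol(p):1, , drop = FALSE]
  expect_identical(flip(flip(pixels(im))), pixels(im))
  expect_identical(mirror(mirror(pixels(im))), pixels(im))
})

test_that("stratified split honours floor allocation with remainder to train", {
  mkManifest <- function(n, classes = "A", organs = "seed") {
    do.call(rbind, lapply(classes, function(cl)
      do.call(rbind, lapply(organs, function(org)
        data.frame(path = sprintf("%s_%s_%04d.png", cl, org, seq_len(n)),
                   class = cl, organ = org, scan_id = "s",
                   object_index = seq_len(n), area_px = 100L,
                   split = "unassigned", stringsAsFactors = FALSE)))))
  }
  for (case in list(c(1000L, 800L, 100L, 100L),
                    c(10L, 8L, 1L, 1L),
                    c(1001L, 801L, 100L, 100L))) {
    sp <- splitManifest(mkManifest(case[1]), seed = 4)
    tab <- table(sp$split)
    expect_identical(as.integer(tab[c("train", "val", "test")]),
                     case[2:4])
  }
  # stratified over groups, conserved counts, no duplicates
  m <- mkManifest(40L, classes = c("A", "B"), organs = c("pod", "seed"))
  sp <- splitManifest(m, seed = 1)
  for (cl in c("A", "B")) for (org in c("pod", "seed")) {
    tab <- table(sp$split[sp$class == cl & sp$organ == org])
    expect_identical(as.integer(tab[c("train", "val", "test")]),
                     c(32L, 4L, 4L))
  }
  expect_false(anyDuplicated(sp$path) > 0)
  # reproducible
  expect_identical(sp, splitManifest(m, seed = 1))
  expect_false(identical(sp$split, splitManifest(m, seed = 2)$split))
  expect_error(splitManifest(mkManifest(2L)), "smaller than 3")
})

test_that("disk augmentation balances groups and guards against leakage", {
  dir <- tempfile("aug")
  manifest <- writeObjectFixtures(dir, nPerClass = 10L)
  pol <- augmentationPolicy(seed = 13)

  # split-before-augment: only train rows augmented, to the train share
  res <- augmentManifest(manifest, targetPerGroup = 20L, policy = pol,
                         mode = "split_before_augment", seed = 3)
  for (cl in c("A", "B")) {
    rows <- res[res$class == cl, ]
    expect_identical(sum(rows$split == "train"), 16L)    # 8/10 of 20
    expect_identical(sum(rows$split == "val"), 1L)
    expect_identical(sum(rows$split == "test"), 1L)
  }
  aug <- res[res$is_augmented, ]
  expect_true(all(aug$split == "train"))
  src <- res$split[match(aug$source_path, res$path)]
  expect_true(all(src == "train"))                       # leakage guard
  expect_true(all(file.exists(aug$path)))
  expect_true(all(grepl("_aug[0-9]{3}\\.png$", aug$path)))

  # classical order: augment each group to target, then split the full group
  dir2 <- tempfile("aug2")
  manifest2 <- writeObjectFixtures(dir2, nPerClass = 10L)
  res2 <- augmentManifest(manifest2, targetPerGroup = 20L, policy = pol,
                          mode = "augment_then_split", seed = 3)
  for (cl in c("A", "B")) {
    tab <- table(res2$split[res2$class == cl])
    expect_identical(as.integer(tab[c("train", "val", "test")]),
                     c(16L, 2L, 2L))
  }
  expect_identical(sum(res2$class == "A"), 20L)
})

test_that("augmentation policy validates its fields", {
  expect_error(augmentationPolicy(ops = character()), "at least one")
  expect_error(augmentationPolicy(ops = "sharpen"), "unknown ops")
  expect_error(augmentationPolicy(shiftMaxFraction = 0.5), "0, 0.2")
})
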