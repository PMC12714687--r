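test_that("a straight 3 mm tube is recovered within 2 voxels at 0.2083 mm", {
  h <- 0.2083
  tube <- tubeMap(3, h, length_mm = 8, off = c(0.07, 0.12))
  lt <- localThickness(tube)
  cls <- labelCenterlines(tube, labels = 2L)
  res <- arteryDiameter(tube, 2L, lt, cls)
  expect_lt(abs(res$diameter_mm - 3), 2 * h)
  expect_gt(res$n_centerline_voxels, 0)
  expect_identical(res$flags, "")
})

test_that("absent labels and thin vessels are flagged", {
  h <- 0.625
  tube <- tubeMap(1, h, length_mm = 8)
  lt <- localThickness(tube)
  cls <- labelCenterlines(tube, labels = c(2L))
  thin <- arteryDiameter(tube, 2L, lt, cls)
  expect_match(thin$flags, "TOO_THIN")
  expect_false(is.na(thin$diameter_mm))

  # an absent label yields a missing diameter with the ABSENT flag
  voc <- c(labelVocabulary(tube), `5` = "ACA-A1-R")
  tube2 <- labelMap(gridValues(tube), spacing = gridSpacing(tube),
                    origin = gridOrigin(tube), vocabulary = voc)
  cls2 <- labelCenterlines(tube2, labels = c(2L, 5L))
  lt2 <- localThickness(tube2)
  absent <- arteryDiameter(tube2, 5L, lt2, cls2)
  expect_true(is.na(absent$diameter_mm))
  expect_identical(absent$flags, "ABSENT")

  # inputs from different resolutions are rejected
  coarse <- resampleNearest(tube, 1.25)
  expect_error(arteryDiameter(coarse, 2L, lt, cls), "mismatch")
})

test_that("PCom rule keeps connected PComs and drops disconnected ones", {
  ph <- makeCowPhantom(voxel_mm = 0.5, jitter_sd = 0, seed = 7,
                       world_offset = c(0, 0, 0))
  res <- measureArteries(ph$labelmap)
  pcom <- res[res$artery == "PCom", ]
  expect_false(any(is.na(pcom$diameter_mm)))
  expect_false(any(grepl("PCOM_DISCONNECTED", pcom$flags)))

  # carve a one-voxel gap between PCom-R and the PCA: rule must exclude it
  v <- gridValues(ph$labelmap)
  pca <- which(v == 11L, arr.ind = TRUE)
  pcomv <- which(v == 9L, arr.ind = TRUE)
  for (r in seq_len(nrow(pcomv))) {
    p <- pcomv[r, ]
    if (any(abs(pca[, 1] - p[1]) <= 1 & abs(pca[, 2] - p[2]) <= 1 &
              abs(pca[, 3] - p[3]) <= 1))
      v[p[1], p[2], p[3]] <- 0L
  }
  carved <- labelMap(v, spacing = gridSpacing(ph$labelmap),
                     origin = gridOrigin(ph$labelmap),
                     vocabulary = labelVocabulary(ph$labelmap))
  res2 <- measureArteries(carved)
  pr <- res2[res2$artery == "PCom" & res2$side == "R", ]
  expect_true(is.na(pr$diameter_mm))
  expect_match(pr$flags, "PCOM_DISCONNECTED")
  # the left PCom is untouched
  pl <- res2[res2$artery == "PCom" & res2$side == "L", ]
  expect_false(is.na(pl$diameter_mm))
})

test_that("measureAll emits 11 finite automated measurements on the default phantom", {
  ph <- makeCowPhantom(voxel_mm = 0.4, seed = 12)
  tab <- measureAll(ph$labelmap, participant_id = "p1")
  expect_equal(nrow(tab), 11)
  expect_true(all(tab$source == "auto"))
  expect_true(all(!is.na(tab$diameter_mm)))
  expect_true(all(tab$diameter_mm > 0 & is.finite(tab$diameter_mm)))

  # determinism: identical input gives an identical table
  expect_identical(measureAll(ph$labelmap, participant_id = "p1"), tab)

  # fetal variant: left P1 missing, left PCom still measured (via P2)
  fet <- makeCowPhantom(voxel_mm = 0.4, seed = 12,
                        variants = "fetal_pca_left")
  ft <- measureAll(fet$labelmap)
  expect_true(is.na(ft$diameter_mm[ft$artery == "PCA-P1" & ft$side == "L"]))
  expect_false(is.na(ft$diameter_mm[ft$artery == "PCom" & ft$side == "L"]))
})

test_that("resolution study returns one table per size and inflates with voxel size", {
  ph <- makeCowPhantom(voxel_mm = 0.4, seed = 3)
  st <- resolutionStudy(ph$labelmap, sizes = c(0.4, 0.8))
  expect_named(st, c("0.4", "0.8"))
  expect_true(all(vapply(st, nrow, 0L) == 11))

  # per-size segmentation: positive partial-volume bias, larger when coarse
  sub <- cwEnsembleStudy(n_phantoms = 4, sizes = c(0.2083, 0.625), seed = 50)
  bias <- aggregate(diameter_mm - true_diameter_mm ~ size_mm, sub, mean)
  expect_gt(bias[bias$size_mm == 0.625, 2], 0)
  expect_gt(bias[bias$size_mm == 0.625, 2], bias[bias$size_mm == 0.2083, 2])
})

test_that("kissing tubes merge below one voxel gap and separate above it", {
  h <- 0.625
  merged <- makeKissingPair(c(4, 4), gap_mm = 0.1, voxel_mm = h)
  expect_equal(nComponents26(gridValues(merged) > 0), 1L)
  expect_equal(nComponents26(gridValues(
    makeKissingPair(c(4, 4), gap_mm = 0, voxel_mm = h)) > 0), 1L)

  apart <- makeKissingPair(c(4, 4), gap_mm = 1.0, voxel_mm = 0.2083)
  expect_equal(nComponents26(gridValues(apart) > 0), 2L)

  # merging can only raise local thickness where the isolated tube exists
  iso <- makeKissingPair(c(4, 4), gap_mm = 0.1, voxel_mm = h,
                         isolated = TRUE)
  lt_m <- gridValues(localThickness(merged))
  lt_i <- gridValues(localThickness(iso))
  fg <- gridValues(iso) > 0
  expect_true(all(lt_m[fg] >= lt_i[fg] - 1e-12))

  # well-separated at fine h: estimate matches the isolated tube within 2h
  iso_f <- makeKissingPair(c(4, 4), gap_mm = 1.0, voxel_mm = 0.2083,
                           isolated = TRUE)
  expect_lt(abs(maskDiameter(apart) - maskDiameter(iso_f)), 2 * 0.2083)
})
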