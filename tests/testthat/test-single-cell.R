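test_that("overlap resolution splits a symmetric lens along the bisector and
           matches the exhaustive oracle", {
  m1 <- diskMask(48, 10, c(24, 18))
  m2 <- diskMask(48, 10, c(24, 30))
  lm <- resolveOverlaps(list(m1, m2))
  oracle <- bruteResolve(list(m1, m2))
  expect_identical(lm@labels, oracle)
  # contested pixels split by the vertical bisector between centers
  contested <- m1 & m2
  left <- contested & col(m1) < 24
  right <- contested & col(m1) > 24
  expect_true(all(lm@labels[left] %in% c(0L, 1L)))
  expect_true(all(lm@labels[right] %in% c(0L, 2L)))
})

test_that("non-overlapping masks stack unchanged", {
  m1 <- diskMask(40, 6, c(12, 12))
  m2 <- diskMask(40, 6, c(30, 30))
  lm <- resolveOverlaps(list(m1, m2), probabilities = c(0.8, 0.9))
  expect_identical(lm@labels == 1L, m1)
  expect_identical(lm@labels == 2L, m2)
  expect_equal(lm@probabilities, c(0.8, 0.9))
})

test_that("overlap resolution agrees with the oracle on random fixtures", {
  set.seed(17)
  for (rep in 1:3) {
    masks <- lapply(1:4, function(i) {
      diskMask(36, runif(1, 4, 8), c(runif(1, 10, 26), runif(1, 10, 26)))
    })
    lm <- resolveOverlaps(masks)
    expect_identical(lm@labels, bruteResolve(masks))
  }
})

test_that("a nested mask survives only where its distance map wins", {
  big <- diskMask(40, 12, c(20, 20))
  small <- diskMask(40, 4, c(20, 20))
  lm <- resolveOverlaps(list(big, small))
  oracle <- bruteResolve(list(big, small))
  expect_identical(lm@labels, oracle)
  # the small nested object is entirely dominated here
  expect_identical(sort(unique(as.integer(lm@labels))), c(0L, 1L))
})

test_that("probability filtering keeps the boundary and re-densifies ids", {
  labels <- matrix(0L, 12, 12)
  labels[2:3, 2:3] <- 1L; labels[6:7, 6:7] <- 2L; labels[10:11, 10:11] <- 3L
  lm <- LabelMap(labels, probabilities = c(0.9, 0.4, 0.5))
  out <- filterByProbability(lm, 0.5)
  expect_equal(length(out@probabilities), 2L)
  expect_equal(out@probabilities, c(0.9, 0.5))
  expect_identical(unique(as.integer(out@labels[6:7, 6:7])), 0L)
  expect_identical(unique(as.integer(out@labels[10:11, 10:11])), 2L)
  idMap <- attr(out, "idMap")
  expect_equal(idMap$old_id, c(1L, 3L))
  # minP = 0 is the identity; all-below empties the map
  expect_identical(filterByProbability(lm, 0)@labels, lm@labels)
  none <- filterByProbability(lm, 0.95)
  expect_equal(length(none@probabilities), 0L)
  expect_true(all(none@labels == 0L))
})

test_that("cell expansion caps area at the ratio and floors correctly", {
  labels <- matrix(0L, 60, 60)
  labels[21:30, 21:30] <- 1L                      # 100-px square nucleus
  cz <- expandCells(LabelMap(labels), radiusUm = 10, maxAreaRatio = 1.5)
  expect_equal(sum(cz@cellLabels == 1L), 150L)    # floor(1.5 * 100)
  # radius 0: cell = nucleus, cytoplasm empty
  cz0 <- expandCells(LabelMap(labels), radiusUm = 0)
  expect_identical(cz0@cellLabels, cz0@nucleusLabels)
  zl <- hyperplexR:::zoneLabelMatrices(cz0)
  expect_true(all(zl$cytoplasm == 0L))
})

test_that("expansion frontiers of adjacent nuclei meet at the equidistant
           line and cells stay disjoint", {
  labels <- matrix(0L, 40, 40)
  labels[19:21, 14:16] <- 1L                      # centers 3 um apart
  labels[19:21, 17 + 0:2] <- 2L
  cz <- expandCells(LabelMap(labels, pixelSize = 1), radiusUm = 2.5,
                    maxAreaRatio = 10)
  lab <- cz@cellLabels
  # oracle: nearest-nucleus distance transform per pixel
  px1 <- which(labels == 1L, arr.ind = TRUE)
  px2 <- which(labels == 2L, arr.ind = TRUE)
  for (idx in which(lab > 0L & labels == 0L)) {
    r <- (idx - 1) %% 40 + 1; c <- (idx - 1) %/% 40 + 1
    d1 <- min((px1[, 1] - r)^2 + (px1[, 2] - c)^2)
    d2 <- min((px2[, 1] - r)^2 + (px2[, 2] - c)^2)
    expect_identical(lab[idx], if (d1 <= d2) 1L else 2L)
  }
  expect_equal(sum(lab == 1L & labels == 2L), 0L)
})

test_that("zone partition and cap hold for hundreds of expanded cells", {
  sim <- makeNucleiImage(n = 120L, shape = c(512L, 512L), density = 0.5,
                         seed = 18)
  cz <- expandCells(sim$labels, radiusUm = 2.5, maxAreaRatio = 1.5)
  zl <- hyperplexR:::zoneLabelMatrices(cz)
  nObj <- length(cz@probabilities)
  areaN <- tabulate(zl$nucleus[zl$nucleus > 0], nObj)
  areaCyto <- tabulate(zl$cytoplasm[zl$cytoplasm > 0], nObj)
  areaCell <- tabulate(zl$cell[zl$cell > 0], nObj)
  # nucleus + cytoplasm partition the cell, and the cap binds everywhere
  expect_equal(areaN + areaCyto, areaCell)
  expect_true(all(zl$nucleus == 0L | zl$cytoplasm == 0L))
  expect_true(all(areaCell <= 1.5 * areaN + 1))
  # membrane lies inside the cell
  memIdx <- zl$membrane > 0L
  expect_true(all(zl$cell[memIdx] == zl$membrane[memIdx]))
})

test_that("measurements: constant field MFI, disk circularity, analytic
           region distance, exclusion", {
  labels <- matrix(0L, 80, 80)
  labels[diskMask(80, 10, c(40, 20))] <- 1L
  labels[diskMask(80, 6, c(40, 60))] <- 2L
  lm <- LabelMap(labels, probabilities = c(0.9, 0.7), pixelSize = 1)
  cz <- expandCells(lm, radiusUm = 2)
  stack <- HyperplexStack(list(ChannelImage(matrix(1000, 80, 80), 1, "mk")))
  half <- matrix(FALSE, 80, 80); half[, 1:45] <- TRUE
  excl <- matrix(FALSE, 80, 80); excl[, 46:80] <- TRUE
  regions <- RegionSet(list(RegionMask(half, "tumor"),
                            RegionMask(excl, "excluded")))
  tab <- measureCells(stack, cz, regions)
  # cell 2 sits in the excluded region and is dropped
  expect_equal(tab$cell_id, 1L)
  mfiCols <- grep("^mfi__", colnames(tab), value = TRUE)
  expect_true(all(abs(unlist(tab[mfiCols]) - 1000) < 1e-9))
  expect_gte(tab$nucleus_circularity, 0.95)
  expect_lte(tab$nucleus_circularity, 1.0)
  # centroid at col 20 (0-based 19), region edge between cols 45 and 46
  # (geometric edge 25.5 px away); boundary-pixel distance is 25.5 +- 0.5
  expect_lt(abs(tab$dist__tumor - 25.5), 0.5 + 1e-9)
  expect_true(tab$in__tumor)
  expect_equal(tab$probability, 0.9)
})

test_that("empty zones are missing, not zero", {
  labels <- matrix(0L, 20, 20); labels[10, 10] <- 1L
  cz <- expandCells(LabelMap(labels), radiusUm = 0)
  stack <- HyperplexStack(list(ChannelImage(matrix(500, 20, 20), 1, "mk")))
  tab <- measureCells(stack, cz)
  expect_true(is.na(tab$mfi__mk__cytoplasm))
  expect_equal(tab$mfi__mk__nucleus, 500)
})

test_that("watershed baseline finds separated nuclei near their true
           centers", {
  sim <- makeNucleiImage(n = 20L, shape = c(256L, 256L), density = 0.1,
                         irregularity = 0.1, seed = 19)
  seg <- baselineWatershedSegment(sim$dapi, smoothingSigma = 2,
                                  minAreaPx = 20)
  expect_equal(length(seg@probabilities), 20L)
  found <- hyperplexR:::labelCentroids(seg@labels)
  for (i in seq_len(nrow(sim$centers))) {
    d <- sqrt(rowSums((found - matrix(sim$centers[i, ], nrow(found), 2,
                                      byrow = TRUE))^2))
    expect_lt(min(d), 1.5)
  }
  blank <- baselineWatershedSegment(ChannelImage(matrix(0, 64, 64), 1,
                                                 "DAPI"))
  expect_equal(length(blank@probabilities), 0L)
})

test_that("label maps round-trip through TIFF with probabilities", {
  sim <- makeNucleiImage(n = 10L, shape = c(96L, 96L), seed = 20)
  lm <- sim$labels
  lm@probabilities <- runif(length(lm@probabilities))
  tf <- withr::local_tempfile(fileext = ".tif")
  writeLabelMap(lm, tf)
  back <- readLabelMap(tf)
  expect_identical(back@labels, lm@labels)
  expect_equal(back@probabilities, lm@probabilities, tolerance = 1e-12)
})

test_that("size filtering drops fragments below the area threshold", {
  labels <- matrix(0L, 30, 30)
  labels[2:3, 2:3] <- 1L            # 4 px
  labels[10:15, 10:15] <- 2L        # 36 px
  lm <- LabelMap(labels, pixelSize = 0.5)   # areas 1 and 9 um^2
  out <- filterBySize(lm, minAreaUm2 = 4)
  expect_equal(length(out@probabilities), 1L)
  expect_true(all(out@labels[10:15, 10:15] == 1L))
})
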