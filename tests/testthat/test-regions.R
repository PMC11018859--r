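test_that("clean_mask fills small holes, drops small fragments, and is
           idempotent", {
  m <- diskMask(60, 18)
  m[30:32, 30:32] <- FALSE                       # 9-px hole
  frag15 <- diskMask(60, 2, c(8, 8))             # ~13 px
  frag30 <- diskMask(60, 3, c(52, 52))           # ~29 px
  mask <- RegionMask(m | frag15 | frag30, "lesion")

  cleaned <- cleanMask(mask, minHolePx = 20, minFragmentPx = 20)
  expect_true(all(cleaned@mask[30:32, 30:32]))   # hole below threshold filled
  expect_false(any(cleaned@mask[1:12, 1:12]))    # 13-px fragment removed
  expect_true(any(cleaned@mask[49:56, 49:56]))   # 29-px fragment kept
  # idempotent
  again <- cleanMask(cleaned, minHolePx = 20, minFragmentPx = 20)
  expect_identical(again@mask, cleaned@mask)
  # zero thresholds are a no-op
  expect_identical(cleanMask(mask, 0, 0)@mask, mask@mask)
})

test_that("clean_mask fragment removal agrees with a labeling oracle", {
  set.seed(15)
  m <- matrix(runif(70 * 70) < 0.35, 70, 70)
  mask <- RegionMask(m, "ecm")
  cleaned <- cleanMask(mask, minHolePx = 0, minFragmentPx = 12)
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  areas <- table(lab[lab > 0])
  expected <- matrix(as.matrix(lab) %in%
                       as.integer(names(areas)[areas >= 12]), 70, 70)
  expect_identical(cleaned@mask, expected)
})

test_that("expand_region matches Euclidean geometry and a distance oracle", {
  # disk radius 10 expanded by 5 px-equivalent um -> disk radius 15
  m <- RegionMask(diskMask(64, 10), "lesion", pixelSize = 1)
  grown <- expandRegion(m, 5)
  expect_lt(abs(sum(grown@mask) - pi * 15^2) / (pi * 15^2), 0.03)
  expect_true(all(grown@mask[m@mask]))           # contains input
  # distance 0 -> identity
  expect_identical(expandRegion(m, 0)@mask, m@mask)
  # monotone in distance
  expect_true(all(expandRegion(m, 8)@mask[expandRegion(m, 4)@mask]))
  # perivascular band of a 1-px line, 15 um at 1 um/px -> 31-px-wide band
  # minus the line; oracle = per-pixel distance to the line
  line <- matrix(FALSE, 41, 41); line[, 21] <- TRUE
  peri <- expandRegion(RegionMask(line, "vessel"), 15, subtractCore = TRUE)
  dcol <- abs(col(line) - 21)
  expect_identical(peri@mask, dcol <= 15 & dcol > 0)
})

test_that("derive_border builds a centered band over the interface", {
  tumor <- RegionMask(col(matrix(0, 300, 300)) <= 150, "tumor")
  brain <- RegionMask(!tumor@mask, "brain")
  border <- deriveBorder(tumor, brain, widthUm = 70)
  # vertical band of total width ~141 px centered on the interface
  widths <- rowSums(border@mask)
  expect_true(all(widths >= 140 & widths <= 143))
  cols <- which(colSums(border@mask) > 0)
  expect_true(150 %in% cols && 151 %in% cols)
  # width 0 -> just the interface pixels
  thin <- deriveBorder(tumor, brain, widthUm = 0)
  expect_identical(sort(unique(which(thin@mask, arr.ind = TRUE)[, 2])),
                   c(150L, 151L))
  # non-touching masks give an empty border with a warning
  t2 <- RegionMask(diskMask(200, 10, c(40, 40)), "tumor")
  b2 <- RegionMask(diskMask(200, 10, c(160, 160)), "brain")
  expect_warning(empty <- deriveBorder(t2, b2), "do not touch")
  expect_false(any(empty@mask))
})

test_that("derived niches are reproducible functions of the base masks", {
  vessel <- RegionMask(diskMask(120, 3, c(60, 60)), "vessel")
  lesion <- RegionMask(diskMask(120, 25, c(60, 60)), "lesion")
  tumor <- RegionMask(diskMask(120, 20, c(60, 60)), "tumor")
  brain <- RegionMask(!tumor@mask, "brain")
  rs <- RegionSet(list(lesion, vessel, tumor, brain))
  a <- deriveNiches(rs, lesionContextUm = 30)
  b <- deriveNiches(rs, lesionContextUm = 30)
  expect_setequal(regionNames(a),
                  c("lesion", "vessel", "tumor", "brain", "lesion_context",
                    "perivascular", "border"))
  for (nm in regionNames(a)) {
    expect_identical(getRegion(a, nm)@mask, getRegion(b, nm)@mask)
    expect_identical(getRegion(a, nm)@provenance,
                     if (nm %in% c("lesion_context", "perivascular", "border"))
                       "derived" else "imported")
  }
  expect_false(any(getRegion(a, "perivascular")@mask & vessel@mask))
})

test_that("the baseline pixel classifier separates intensity-defined
           regions", {
  set.seed(16)
  n <- 96
  truth <- matrix(FALSE, n, n); truth[, 1:48] <- TRUE
  ch1 <- matrix(rnorm(n * n, 500, 150), n); ch1[truth] <- rnorm(sum(truth), 6000, 500)
  ch2 <- matrix(rnorm(n * n, 2000, 400), n)
  stack <- HyperplexStack(list(ChannelImage(pmax(ch1, 0), 1, "CD31"),
                               ChannelImage(pmax(ch2, 0), 1, "WGA")))
  scribbles <- matrix(0L, n, n)
  scribbles[20:70, 5:15] <- 1L
  scribbles[20:70, 80:90] <- 2L
  mask <- classifyPixels(stack, c("CD31", "WGA"), scribbles, label = "vessel",
                         seed = 3)
  jac <- sum(mask@mask & truth) / sum(mask@mask | truth)
  expect_gte(jac, 0.95)
  expect_identical(mask@provenance, "classifier")
  # one-class scribbles are a contract violation
  bad <- matrix(0L, n, n); bad[1:5, 1:5] <- 1L
  expect_error(classifyPixels(stack, "CD31", bad), "positive and.*negative")
  expect_error(classifyPixels(stack, "CD13", scribbles), "absent")
})

test_that("imported masks pass through untouched with provenance recorded", {
  m <- diskMask(40, 9)
  mask <- importMask(m, "excluded", pixelSize = 0.5)
  expect_identical(mask@mask, m)
  expect_identical(mask@provenance, "imported")
})

test_that("masks round-trip through GeoJSON and TIFF", {
  m <- RegionMask(diskMask(64, 14), "tumor", pixelSize = 2)
  gj <- withr::local_tempfile(fileext = ".geojson")
  writeRegionGeoJSON(m, gj)
  back <- readRegionGeoJSON(gj, dims = c(64, 64), pixelSize = 2)
  expect_identical(back@label, "tumor")
  agree <- sum(back@mask & m@mask) / sum(back@mask | m@mask)
  expect_gte(agree, 0.9)                          # raster/polygon tolerance
  tf <- withr::local_tempfile(fileext = ".tif")
  writeMaskTIFF(m, tf)
  back2 <- readMaskTIFF(tf)
  expect_identical(back2@mask, m@mask)
  expect_equal(back2@pixelSize, 2)
  expect_identical(back2@label, "tumor")
})
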