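test_that("a three-round experiment aligns to sub-pixel landmark agreement", {
  sim <- makeCyclicRounds(shape = c(256L, 256L), nRounds = 3L, nNuclei = 120L,
                          withAfRound = FALSE, afAmplitude = 800, seed = 5)
  stack <- alignExperiment(sim$rounds)
  tr <- attr(stack, "transforms")
  for (k in 2:3) {
    tEst <- tr[[paste0("round", k)]]
    back <- transformPoints(tEst, sim$truth$landmarksPerRound[[k]])
    rms <- sqrt(mean(rowSums((back - sim$truth$landmarks)^2)))
    expect_lt(rms, 0.5)
  }
  # channel bookkeeping: one DAPI (round 1) + 2 markers per round
  expect_equal(nChannels(stack), 1L + 3L * 2L)
  expect_identical(channelNames(stack)[1], "DAPI")
})

test_that("a single round passes through unchanged", {
  sim <- makeCyclicRounds(shape = c(96L, 96L), nRounds = 1L, nNuclei = 25L,
                          withAfRound = FALSE, seed = 6)
  stack <- alignExperiment(sim$rounds)
  expect_equal(imageData(stack, 1), imageData(sim$rounds[[1]], 1),
               ignore_attr = TRUE)
  expect_equal(imageData(stack, 2), imageData(sim$rounds[[1]], 2),
               ignore_attr = TRUE)
})

test_that("autofluorescence subtraction applies to markers but not the skip
           list, and never yields negatives", {
  sim <- makeCyclicRounds(shape = c(192L, 192L), nRounds = 2L, nNuclei = 70L,
                          afAmplitude = 2000, seed = 9)
  stackSkip <- alignExperiment(sim$rounds, afRound = sim$afRound,
                               skipAfChannels = "M1")
  stackAll <- alignExperiment(sim$rounds, afRound = sim$afRound)
  stackNone <- alignExperiment(sim$rounds)
  # skip-listed channel is bit-identical to its warped-only version
  expect_identical(imageData(stackSkip, "M1"), imageData(stackNone, "M1"))
  # non-skipped channel differs (AF was removed) and drops in intensity
  expect_gt(mean(imageData(stackNone, "M2")), mean(imageData(stackAll, "M2")))
  expect_false(identical(imageData(stackAll, "M1"),
                         imageData(stackNone, "M1")))
  for (i in seq_len(nChannels(stackAll))) {
    expect_gte(min(imageData(stackAll, i)), 0)
  }
})

test_that("autofluorescence removal recovers the marker component", {
  # noise-free rounds: channel = marker + AF exactly, identity transforms
  sim <- makeCyclicRounds(shape = c(128L, 128L), nRounds = 1L, nNuclei = 40L,
                          transforms = list(PlanarTransform()),
                          afAmplitude = 1500, noise = FALSE, seed = 10)
  stack <- alignExperiment(sim$rounds, afRound = sim$afRound)
  for (m in c("M1", "M2")) {
    residual <- imageData(stack, m) - sim$truth$markerScenes[[m]]
    expect_lt(mean(abs(residual)), 0.01 * 1500)
  }
})

test_that("registration failure aborts unless forced", {
  flat <- RoundStack(list(ChannelImage(matrix(10, 64, 64), 0.5, "DAPI")))
  sim <- makeCyclicRounds(shape = c(64L, 64L), nRounds = 1L, nNuclei = 12L,
                          withAfRound = FALSE, seed = 12)
  expect_error(alignExperiment(list(sim$rounds[[1]], flat)), "round 2")
  expect_warning(stack <- alignExperiment(list(sim$rounds[[1]], flat),
                                          force = TRUE),
                 "unregistered")
  expect_equal(nChannels(stack), 3L + 1L - 1L)
})

test_that("keepDapi = 'all' retains each round's DAPI with unique names", {
  sim <- makeCyclicRounds(shape = c(128L, 128L), nRounds = 2L, nNuclei = 40L,
                          withAfRound = FALSE, seed = 13)
  stack <- alignExperiment(sim$rounds, keepDapi = "all")
  expect_setequal(channelNames(stack),
                  c("DAPI_r1", "DAPI_r2", "M1", "M2", "M3", "M4"))
})

test_that("transform sidecars serialize matrices and residuals", {
  sim <- makeCyclicRounds(shape = c(128L, 128L), nRounds = 2L, nNuclei = 40L,
                          withAfRound = FALSE, seed = 14)
  stack <- alignExperiment(sim$rounds)
  tf <- withr::local_tempfile(fileext = ".json")
  writeTransforms(stack, tf)
  j <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_named(j, c("round1", "round2"))
  expect_equal(dim(j$round2$matrix), c(2, 3))
  expect_equal(j$round2$matrix,
               attr(stack, "transforms")$round2@matrix, ignore_attr = TRUE)
})

test_that("the streaming disk-to-disk alignment matches the in-memory
           pipeline", {
  sim <- makeCyclicRounds(shape = c(160L, 160L), nRounds = 2L, nNuclei = 50L,
                          afAmplitude = 1200, seed = 15)
  dirIn <- withr::local_tempdir()
  paths <- file.path(dirIn, sprintf("round%d.tif", 1:2))
  writeRound(sim$rounds[[1]], paths[1])
  writeRound(sim$rounds[[2]], paths[2])
  afPath <- file.path(dirIn, "af.tif")
  writeRound(sim$afRound, afPath)
  outDir <- withr::local_tempdir()
  alignExperimentDir(paths, outDir, afPath = afPath,
                     skipAfChannels = "M1")
  streamed <- readAlignedDir(outDir)
  inMem <- alignExperiment(sim$rounds, afRound = sim$afRound,
                           skipAfChannels = "M1")
  expect_identical(channelNames(streamed), channelNames(inMem))
  for (nm in channelNames(inMem)) {
    # same registration and warping; small differences come from 16-bit
    # write quantization of intermediate channels (< 0.5 each for the
    # marker, the warped AF image, and the final write)
    expect_lt(max(abs(imageData(streamed, nm) - imageData(inMem, nm))), 2.5)
  }
})
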