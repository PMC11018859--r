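test_that("marker scaling clips at the quantile and lands in [0, 1]", {
  tab <- data.frame(mfi__a__cell = seq(0, 1000, length.out = 1001),
                    mfi__b__nucleus = c(seq(1, 100, length.out = 1000), 1e6))
  cfg <- c(a = "cell", b = "nucleus")
  sc <- scaleMarkers(tab, cfg, clipQuantile = 0.997)
  X <- sc$features
  expect_true(all(X >= 0 & X <= 1))
  # the 99.7th-percentile value maps to 1, larger values too
  qa <- unname(quantile(tab$mfi__a__cell, 0.997))
  expect_equal(unname(X[tab$mfi__a__cell >= qa, "a"]),
               rep(1, sum(tab$mfi__a__cell >= qa)))
  # one extreme outlier no longer dominates: the largest non-outlier value
  # scales to ~1
  expect_gte(X[1000, "b"], 0.99)
  expect_equal(max(X[, "b"]), 1)
})

test_that("constant markers scale to zero with a warning", {
  tab <- data.frame(mfi__a__cell = rep(7, 10), mfi__b__cell = 1:10)
  expect_warning(sc <- scaleMarkers(tab, c(a = "cell", b = "cell")),
                 "constant")
  expect_true(all(sc$features[, "a"] == 0))
})

test_that("scaling parameters transfer to new data", {
  tab <- data.frame(mfi__a__cell = runif(100, 0, 100))
  sc <- scaleMarkers(tab, c(a = "cell"))
  Xnew <- applyScaling(matrix(c(-5, 50, 1e5), ncol = 1,
                              dimnames = list(NULL, "a")), sc$scaling)
  expect_equal(unname(Xnew[3, 1]), 1)
  expect_gte(min(Xnew), 0)
})

phenotypeFixture <- function(nCells = 10000L, seed = 21L) {
  centroids <- rbind(c(900, 100, 100, 100, 100),
                     c(100, 900, 100, 100, 100),
                     c(100, 100, 900, 100, 100),
                     c(100, 100, 100, 900, 100),
                     c(100, 100, 100, 100, 900))
  sim <- makeMarkerTable(nCells, centroids, withinSd = 80, seed = seed)
  cfg <- stats::setNames(rep("cell", 5), paste0("M", 1:5))
  sc <- scaleMarkers(sim$table, cfg)
  list(sim = sim, features = sc$features)
}

test_that("the SOM is deterministic and concentrates codebooks on the
           planted phenotypes", {
  fx <- phenotypeFixture(4000L)
  m1 <- trainSOM(fx$features, seed = 3)
  m2 <- trainSOM(fx$features, seed = 3)
  expect_identical(m1@codebook, m2@codebook)
  nodes <- assignNodes(m1, fx$features)
  # per-node purity of ground-truth labels
  purity <- clusterPurity(nodes, fx$sim$labels)
  expect_gte(purity, 0.9)
  expect_true(all(m1@codebook >= 0 & m1@codebook <= 1))
})

test_that("a single repeated point collapses every codebook onto it", {
  X <- matrix(rep(c(0.3, 0.7), each = 200), 200)
  model <- trainSOM(X, grid = c(5L, 5L), seed = 1)
  expect_lt(max(abs(sweep(model@codebook, 2, c(0.3, 0.7)))), 1e-6)
})

test_that("node assignment is exact nearest-codebook with low-id ties", {
  codebook <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  model <- new("SOMModel", grid = c(2L, 2L), codebook = codebook,
               seed = 1L, epochs = 1L, sigma = c(5, 0.5),
               quantError = 0)
  feats <- rbind(c(0, 0), c(1, 1), c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(assignNodes(model, feats), c(1L, 4L, 1L, 2L))
  # brute-force oracle on random data
  set.seed(22)
  X <- matrix(runif(200), 100, 2)
  got <- assignNodes(model, X)
  oracle <- apply(X, 1, function(x) {
    which.min(colSums((t(codebook) - x)^2))
  })
  expect_equal(got, unname(oracle))
  expect_error(assignNodes(model, matrix(0, 2, 3)), "dimension")
})

test_that("metaclustering is deterministic with trivial limits", {
  fx <- phenotypeFixture(2000L)
  model <- trainSOM(fx$features, seed = 5)
  expect_equal(sort(unique(metaclusterNodes(model, 100))), 1:100)
  expect_equal(unique(metaclusterNodes(model, 1)), 1L)
  expect_error(metaclusterNodes(model, 0))
  expect_error(metaclusterNodes(model, 101))
})

test_that("scale -> SOM -> metacluster recovers well-separated phenotypes", {
  fx <- phenotypeFixture(10000L)
  model <- trainSOM(fx$features, seed = 7)
  meta <- metaclusterNodes(model, 5)
  cl <- meta[assignNodes(model, fx$features)]
  expect_gte(adjustedRand(cl, fx$sim$labels), 0.9)
})

test_that("annotation maps totally or errors naming the missing node", {
  tab <- data.frame(cell_id = 1:4)
  nodes <- c(1L, 2L, 2L, 55L)
  expect_error(annotateCells(tab, nodes, c("1" = "TAM_A", "2" = "Tcell")),
               "55")
  ann <- c("1" = "TAM_A", "2" = "Tcell", "55" = "Tumor_A")
  out <- annotateCells(tab, nodes, ann)
  expect_identical(out$cell_type, c("TAM_A", "Tcell", "Tcell", "Tumor_A"))
  same <- annotateCells(tab, rep(1L, 4), c("1" = "X"))
  expect_identical(unique(same$cell_type), "X")
})

test_that("SOM models round-trip through JSON", {
  fx <- phenotypeFixture(1500L)
  model <- trainSOM(fx$features, seed = 9)
  tf <- withr::local_tempfile(fileext = ".json")
  writeSOMModel(model, tf)
  back <- readSOMModel(tf)$model
  expect_equal(back@codebook, model@codebook, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(assignNodes(back, fx$features),
                   assignNodes(model, fx$features))
})

test_that("marker config and node annotation YAML are validated", {
  cfgFile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Ki67: nucleus", "CD31: cell"), cfgFile)
  cfg <- readMarkerConfig(cfgFile)
  expect_identical(cfg, c(Ki67 = "nucleus", CD31 = "cell"))
  badFile <- withr::local_tempfile(fileext = ".yaml")
  writeLines("Ki67: membrane", badFile)
  expect_error(readMarkerConfig(badFile), "invalid zone")
  annFile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("1: TAM_A", "2: Tumor_A"), annFile)
  ann <- readNodeAnnotation(annFile)
  expect_identical(unname(ann), c("TAM_A", "Tumor_A"))
})
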