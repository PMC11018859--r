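test_that("cyclic-round fixtures are deterministic with faithful landmark
           bookkeeping", {
  a <- makeCyclicRounds(shape = c(96L, 96L), nRounds = 2L, nNuclei = 20L,
                        seed = 50)
  b <- makeCyclicRounds(shape = c(96L, 96L), nRounds = 2L, nNuclei = 20L,
                        seed = 50)
  expect_identical(imageData(a$rounds[[2]], 1), imageData(b$rounds[[2]], 1))
  # identity transforms: DAPI differs between rounds only by noise
  cId <- makeCyclicRounds(shape = c(96L, 96L), nRounds = 2L, nNuclei = 20L,
                          transforms = list(PlanarTransform(),
                                            PlanarTransform()),
                          seed = 51)
  d1 <- imageData(cId$rounds[[1]], 1)
  d2 <- imageData(cId$rounds[[2]], 1)
  expect_lt(mean(abs(d1 - d2)), 3 * sqrt(mean(d1)))
  # declared shift moves landmarks by exactly that vector (pre-noise)
  sh <- makeCyclicRounds(shape = c(96L, 96L), nRounds = 2L, nNuclei = 20L,
                         transforms = list(c(0, 0, 0), c(0, 17.3, -8.6)),
                         seed = 52)
  delta <- sh$truth$landmarks - sh$truth$landmarksPerRound[[2]]
  expect_equal(unname(delta[, 1]), rep(17.3, 20), tolerance = 1e-9)
  expect_equal(unname(delta[, 2]), rep(-8.6, 20), tolerance = 1e-9)
  # transforms pushing most content out of frame are rejected
  expect_error(makeCyclicRounds(shape = c(96L, 96L), nRounds = 2L,
                                transforms = list(c(0, 0, 0), c(0, 90, 0)),
                                nNuclei = 20L, seed = 53),
               "out of frame")
})

test_that("nuclei fixtures honor count, radii and density contracts", {
  low <- makeNucleiImage(n = 20L, shape = c(192L, 192L), density = 0.1,
                         radiusRange = c(5, 8), seed = 54)
  expect_equal(length(low$labels@probabilities), 20L)
  # disjoint at low density: no two labels touch (8-adjacency)
  lab <- low$labels@labels
  touching <- FALSE
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nr <- nrow(lab); nc <- ncol(lab)
    a <- lab[max(1, 1 + dr):min(nr, nr + dr), max(1, 1 + dc):min(nc, nc + dc)]
    b <- lab[max(1, 1 - dr):min(nr, nr - dr), max(1, 1 - dc):min(nc, nc - dc)]
    touching <- touching || any(a > 0 & b > 0 & a != b)
  }
  expect_false(touching)
  # areas within the radius-implied range (with irregularity slack)
  areas <- tabulate(lab[lab > 0], 20L)
  expect_true(all(areas > 0.5 * pi * 5^2))
  expect_true(all(areas < 2.0 * pi * 8^2))
  # high density produces at least one touching pair
  high <- makeNucleiImage(n = 40L, shape = c(128L, 128L), density = 1,
                          seed = 55)
  lab2 <- high$labels@labels
  touching2 <- FALSE
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nr <- nrow(lab2); nc <- ncol(lab2)
    a <- lab2[max(1, 1 + dr):min(nr, nr + dr),
              max(1, 1 + dc):min(nc, nc + dc)]
    b <- lab2[max(1, 1 - dr):min(nr, nr - dr),
              max(1, 1 - dc):min(nc, nc - dc)]
    touching2 <- touching2 || any(a > 0 & b > 0 & a != b)
  }
  expect_true(touching2)
  expect_error(makeNucleiImage(n = 500L, shape = c(64L, 64L), density = 0.1,
                               seed = 56), "packing")
})

test_that("marker tables follow the mixture contract", {
  centroids <- rbind(c(100, 900), c(900, 100))
  exact <- makeMarkerTable(50, centroids, withinSd = 0, seed = 57)
  X <- as.matrix(exact$table[, -1])
  expect_true(all(X == centroids[exact$labels, ]))
  big <- makeMarkerTable(10000, centroids, withinSd = 50,
                         weights = c(0.7, 0.3), seed = 58)
  n1 <- sum(big$labels == 1)
  expect_lt(abs(n1 - 7000), 3 * sqrt(10000 * 0.7 * 0.3))
  expect_gte(min(as.matrix(big$table[, -1])), 0)
  again <- makeMarkerTable(10000, centroids, withinSd = 50,
                           weights = c(0.7, 0.3), seed = 58)
  expect_identical(big$table, again$table)
})

test_that("point patterns realize their declared spatial structure", {
  # CSR intensity within 3 sigma of the Poisson count bound
  pp <- makePointPattern("csr", n = 1000, types = "A",
                         windowUm = c(1000, 1000), seed = 59)
  q <- pp$table
  inQuad <- sum(q$x_um <= 500 & q$y_um <= 500)
  expect_lt(abs(inQuad - 250), 3 * sqrt(1000 * 0.25 * 0.75))
  # segregated bands leave at least the declared gap between types
  seg <- makePointPattern("segregated", n = 400, types = c("A", "B"),
                          gapUm = 200, seed = 60)
  ax <- seg$table$x_um[seg$table$cell_type == "A"]
  bx <- seg$table$x_um[seg$table$cell_type == "B"]
  expect_gte(min(outer(ax, bx, function(a, b) abs(a - b))), 200)
  # shared parents shrink cross-type nearest-neighbor distance vs CSR
  wins <- 0
  for (s in 1:25) {
    cl <- makePointPattern("clustered", 300, c("A", "B"), nParents = 8,
                           clusterSdUm = 25, seed = 600 + s)$table
    cs <- makePointPattern("csr", 300, c("A", "B"), seed = 700 + s)$table
    nnd <- function(tb) {
      ia <- tb$cell_type == "A"; ib <- tb$cell_type == "B"
      mean(bruteNNDist(tb$x_um[ia], tb$y_um[ia], tb$x_um[ib], tb$y_um[ib]))
    }
    wins <- wins + (nnd(cl) < nnd(cs))
  }
  expect_gte(wins, 20)
  expect_error(makePointPattern("csr", 10, c("A", "B"),
                                composition = c(0.5, 0.2)), "sum to 1")
})
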