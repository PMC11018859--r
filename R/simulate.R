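# Synthetic fixtures with known ground truth for every pipeline stage:
# multi-round images with declared transforms and a shared autofluorescence
# field, nuclei images with label-map ground truth, marker tables with
# planted phenotypes, and marked point patterns with controlled spatial
# structure. Everything is deterministic under a master seed; noise is
# Poisson photon noise plus small Gaussian read noise.

smoothRandomField <- function(dims, sigma, amplitude, seed) {
  set.seed(seed)
  sigma <- min(sigma, floor((min(dims) - 1) / 8))  # gblur kernel must fit
  f <- matrix(stats::runif(prod(dims)), dims[1], dims[2])
  f <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(f),
                                                   sigma = sigma)))
  rng <- range(f)
  if (diff(rng) == 0) return(matrix(amplitude / 2, dims[1], dims[2]))
  amplitude * (f - rng[1]) / diff(rng)
}

gaussianBlobs <- function(dims, centers, amp, sigma) {
  img <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]; s <- sigma[i]
    w <- ceiling(3.5 * s)
    rs <- max(1, floor(r0 + 1 - w)):min(dims[1], ceiling(r0 + 1 + w))
    cs <- max(1, floor(c0 + 1 - w)):min(dims[2], ceiling(c0 + 1 + w))
    if (!length(rs) || !length(cs)) next
    g <- exp(-outer((rs - 1 - r0)^2, (cs - 1 - c0)^2, "+") / (2 * s^2))
    img[rs, cs] <- img[rs, cs] + amp[i] * g
  }
  img
}

shotNoise <- function(img, readNoiseSd, seed) {
  set.seed(seed)
  out <- matrix(stats::rpois(length(img), lambda = img), nrow(img), ncol(img))
  out <- out + stats::rnorm(length(img), sd = readNoiseSd)
  clamp(out, 0, 65535)
}

#' Simulate a cyclic-IF experiment with known transforms
#'
#' Builds a reference scene of blob-like nuclei (DAPI) plus per-channel
#' marker blobs on a shared smooth autofluorescence field, then renders
#' each round by sampling the scene through its declared true transform
#' (the same bilinear interpolator used by \code{\link{applyTransform}})
#' and adding Poisson photon noise and Gaussian read noise. Round 1 is the
#' reference; an optional pre-antibody autofluorescence round carries the
#' field (plus DAPI signal in its DAPI channel).
#'
#' @param shape image shape (rows, cols).
#' @param pixelSize micrometres per pixel.
#' @param nRounds number of stained rounds.
#' @param markersPerRound non-DAPI channels per round.
#' @param transforms list of \linkS4class{PlanarTransform} (or
#'   \code{c(thetaDeg, dr, dc)} triples) per round; round 1 defaults to
#'   identity, later rounds to small random rigid perturbations.
#' @param nNuclei number of nuclei in the scene.
#' @param afAmplitude peak autofluorescence intensity (0 disables the
#'   field).
#' @param afSigma smoothness of the autofluorescence field in pixels.
#' @param withAfRound also emit the autofluorescence round.
#' @param noise add photon/read noise (disable for exact-identity checks).
#' @param seed master seed.
#' @return List: \code{rounds} (list of \linkS4class{RoundStack}),
#'   \code{afRound} (or NULL), \code{truth} (transforms, landmark
#'   coordinates in the reference frame and per round, autofluorescence
#'   field, marker scenes).
#' @export
makeCyclicRounds <- function(shape = c(512L, 512L), pixelSize = 0.5,
                             nRounds = 3L, markersPerRound = 2L,
                             transforms = NULL, nNuclei = 250L,
                             afAmplitude = 1500, afSigma = 60,
                             withAfRound = TRUE, noise = TRUE, seed = 1L) {
  set.seed(deriveSeed(seed, "scene"))
  margin <- 24
  centers <- cbind(stats::runif(nNuclei, margin, shape[1] - 1 - margin),
                   stats::runif(nNuclei, margin, shape[2] - 1 - margin))
  sig <- stats::runif(nNuclei, 2.5, 4.5)
  dapiScene <- gaussianBlobs(shape, centers,
                             stats::runif(nNuclei, 2500, 7000), sig) + 120
  markerNamePool <- paste0("M", seq_len(nRounds * markersPerRound))
  markerScenes <- list()
  for (m in markerNamePool) {
    sel <- stats::runif(nNuclei) < 0.4
    markerScenes[[m]] <- gaussianBlobs(
      shape, centers[sel, , drop = FALSE],
      stats::runif(sum(sel), 1500, 5000), sig[sel] * 1.4) + 60
  }
  af <- if (afAmplitude > 0) {
    smoothRandomField(shape, afSigma, afAmplitude, deriveSeed(seed, "af"))
  } else matrix(0, shape[1], shape[2])

  if (is.null(transforms)) {
    set.seed(deriveSeed(seed, "transforms"))
    transforms <- c(list(PlanarTransform()), lapply(seq_len(nRounds - 1L),
      function(k) rigidTransform(stats::runif(1, -2, 2),
                                 stats::runif(1, -25, 25),
                                 stats::runif(1, -25, 25), dim = shape)))
  } else {
    transforms <- lapply(transforms, function(t) {
      if (is(t, "PlanarTransform")) t
      else rigidTransform(t[1], t[2], t[3], dim = shape)
    })
  }
  stopifnot(length(transforms) == nRounds)

  renderRound <- function(sceneChannels, names, t, roundIdx, seedKey) {
    chs <- vector("list", length(sceneChannels))
    for (j in seq_along(sceneChannels)) {
      img <- sceneChannels[[j]] + af
      mov <- if (max(abs(t@matrix - cbind(diag(2), c(0, 0)))) < 1e-12) img
      else cpp_warp_bilinear(img, as.numeric(t(t@matrix)), 0)
      frac <- mean(mov == 0)
      if (frac > 0.5) stop("transform pushes >50% of content out of frame")
      if (noise) mov <- shotNoise(mov, 2, deriveSeed(seed, seedKey, j))
      chs[[j]] <- ChannelImage(clamp(mov, 0, 65535), pixelSize, names[j],
                               roundIdx)
    }
    RoundStack(chs, dapiIndex = 1L)
  }

  rounds <- vector("list", nRounds)
  for (k in seq_len(nRounds)) {
    mnames <- markerNamePool[(k - 1L) * markersPerRound + seq_len(markersPerRound)]
    rounds[[k]] <- renderRound(c(list(dapiScene), markerScenes[mnames]),
                               c("DAPI", mnames), transforms[[k]], k,
                               paste0("round", k))
  }
  afRound <- NULL
  if (withAfRound) {
    zero <- matrix(0, shape[1], shape[2])
    afRound <- renderRound(
      c(list(dapiScene), rep(list(zero), markersPerRound)),
      c("DAPI", paste0("AF", seq_len(markersPerRound))),
      PlanarTransform(), 0L, "af-round")
  }
  landmarks <- centers  # reference-frame 0-based (row, col)
  landmarksPerRound <- lapply(transforms, function(t) {
    transformPoints(invertTransform(t), landmarks)
  })
  list(rounds = rounds, afRound = afRound,
       truth = list(transforms = transforms, landmarks = landmarks,
                    landmarksPerRound = landmarksPerRound, afField = af,
                    markerScenes = markerScenes, dapiScene = dapiScene))
}

#' Simulate a nuclei image with ground-truth labels
#'
#' Places \code{n} blob-shaped nuclei (radial sinusoidal irregularity,
#' non-uniform internal intensity emulating uneven DAPI labeling) with a
#' density-controlled minimum separation; at high density shapes touch.
#' Overlap pixels go to the nucleus whose normalized radius is smaller.
#'
#' @param n number of nuclei.
#' @param shape image shape.
#' @param radiusRange min/max nucleus radius in pixels.
#' @param irregularity radial perturbation amplitude (0 = disks).
#' @param density packing control in (0, 1]: low keeps nuclei disjoint,
#'   high allows touching.
#' @param pixelSize micrometres per pixel.
#' @param seed RNG seed.
#' @return List: \code{dapi} (\linkS4class{ChannelImage}), \code{labels}
#'   (ground-truth \linkS4class{LabelMap}), \code{centers} (0-based
#'   (row, col)), \code{radii}.
#' @export
makeNucleiImage <- function(n = 30L, shape = c(256L, 256L),
                            radiusRange = c(5, 9), irregularity = 0.25,
                            density = 0.3, pixelSize = 1, seed = 1L) {
  set.seed(deriveSeed(seed, "nuclei"))
  sepFactor <- 1.15 * (1 - density) + 0.55 * density
  centers <- matrix(0, 0, 2)
  radii <- numeric(0)
  tries <- 0L
  while (nrow(centers) < n) {
    if ((tries <- tries + 1L) > 400L * n) {
      stop("packing failure: could not place ", n, " nuclei at this density")
    }
    r <- stats::runif(1, radiusRange[1], radiusRange[2])
    p <- c(stats::runif(1, r + 2, shape[1] - 1 - r - 2),
           stats::runif(1, r + 2, shape[2] - 1 - r - 2))
    if (nrow(centers)) {
      d <- sqrt(rowSums((centers - matrix(p, nrow(centers), 2,
                                          byrow = TRUE))^2))
      if (any(d < sepFactor * (radii + r))) next
    }
    centers <- rbind(centers, p)
    radii <- c(radii, r)
  }
  labels <- matrix(0L, shape[1], shape[2])
  normRadius <- matrix(Inf, shape[1], shape[2])
  img <- matrix(0, shape[1], shape[2])
  nHarm <- 3L
  for (k in seq_len(n)) {
    amp <- stats::runif(nHarm, 0, irregularity / nHarm)
    ph <- stats::runif(nHarm, 0, 2 * pi)
    peak <- stats::runif(1, 3000, 6000)
    w <- ceiling(radii[k] * (1 + irregularity) + 1)
    rs <- max(1, floor(centers[k, 1] + 1 - w)):min(shape[1],
                                                   ceiling(centers[k, 1] + 1 + w))
    cs <- max(1, floor(centers[k, 2] + 1 - w)):min(shape[2],
                                                   ceiling(centers[k, 2] + 1 + w))
    dr <- rs - 1 - centers[k, 1]
    dc <- cs - 1 - centers[k, 2]
    dist <- sqrt(outer(dr^2, dc^2, "+"))
    theta <- atan2(matrix(dc, length(dr), length(dc), byrow = TRUE),
                   matrix(dr, length(dr), length(dc)))
    rb <- radii[k] * (1 + Reduce(`+`, lapply(seq_len(nHarm), function(h) {
      amp[h] * sin(h * theta + ph[h])
    })))
    nr <- dist / rb
    ins <- nr <= 1
    won <- ins & nr < normRadius[rs, cs]
    sub <- labels[rs, cs]; sub[won] <- k; labels[rs, cs] <- sub
    subn <- normRadius[rs, cs]; subn[won] <- nr[won]; normRadius[rs, cs] <- subn
    # non-uniform internal texture
    tex <- 0.55 + 0.45 * (0.5 + 0.5 * sin(3 * dist + ph[1]) *
                            cos(2 * theta + ph[2]))
    add <- img[rs, cs]
    add[won] <- peak * tex[won] * (1 - 0.3 * nr[won]^2)
    img[rs, cs] <- pmax(img[rs, cs], add)
  }
  img <- img + 100
  img <- shotNoise(img, 2, deriveSeed(seed, "nuclei-noise"))
  list(dapi = ChannelImage(img, pixelSize, "DAPI"),
       labels = LabelMap(labels, pixelSize = pixelSize),
       centers = centers, radii = radii)
}

#' Simulate a marker table with planted phenotypes
#'
#' Cells are drawn from a Gaussian mixture with the given phenotype
#' centroids in marker space; MFIs are clamped non-negative. Columns use
#' the \code{mfi__<marker>__cell} schema so the table feeds
#' \code{\link{scaleMarkers}} directly.
#'
#' @param nCells number of cells.
#' @param centroids K x M matrix of phenotype centroids (rows = phenotypes,
#'   cols = markers).
#' @param withinSd within-phenotype standard deviation (scalar or
#'   per-marker).
#' @param markerNames marker names (default M1..Mm).
#' @param weights mixture weights (default uniform).
#' @param seed RNG seed.
#' @return List: \code{table} (cell table fragment) and \code{labels}
#'   (true phenotype index per cell).
#' @export
makeMarkerTable <- function(nCells, centroids, withinSd, markerNames = NULL,
                            weights = NULL, seed = 1L) {
  centroids <- as.matrix(centroids)
  K <- nrow(centroids); M <- ncol(centroids)
  markerNames <- markerNames %||% paste0("M", seq_len(M))
  weights <- weights %||% rep(1 / K, K)
  set.seed(deriveSeed(seed, "markers"))
  lab <- sample.int(K, nCells, replace = TRUE, prob = weights)
  X <- centroids[lab, , drop = FALSE] +
    matrix(stats::rnorm(nCells * M, sd = withinSd), nCells, M)
  X <- pmax(X, 0)
  colnames(X) <- paste0("mfi__", markerNames, "__cell")
  table <- data.frame(cell_id = seq_len(nCells), X, check.names = FALSE)
  list(table = table, labels = lab)
}

#' Simulate a marked point pattern with controlled spatial structure
#'
#' Three generators: \code{"csr"} (homogeneous uniform placement of all
#' types), \code{"clustered"} (Neyman-Scott parent-offspring process;
#' shared parents across types plant attraction, separate parents per type
#' plant type-specific clustering) and \code{"segregated"} (types confined
#' to disjoint bands separated by a gap, planting avoidance and spatial
#' niches).
#'
#' @param process one of "csr", "clustered", "segregated".
#' @param n total number of cells.
#' @param types cell-type labels.
#' @param composition type proportions summing to 1 (default uniform).
#' @param windowUm window extent (width, height) in micrometres.
#' @param nParents parent count for the clustered process.
#' @param clusterSdUm offspring dispersion around parents.
#' @param sharedParents clustered process: one parent set for all types
#'   (TRUE) or an independent set per type (FALSE).
#' @param gapUm empty gap between bands in the segregated process.
#' @param imageId,group identifiers stamped on the rows.
#' @param seed RNG seed.
#' @return List: \code{table} (image_id, group, x_um, y_um, cell_type) and
#'   \code{truth} (process parameters; parents for clustered patterns).
#' @export
makePointPattern <- function(process = c("csr", "clustered", "segregated"),
                             n = 500L, types = c("A", "B"),
                             composition = NULL, windowUm = c(1000, 1000),
                             nParents = 10L, clusterSdUm = 30,
                             sharedParents = TRUE, gapUm = 100,
                             imageId = "img1", group = "g1", seed = 1L) {
  process <- match.arg(process)
  composition <- composition %||% rep(1 / length(types), length(types))
  if (abs(sum(composition) - 1) > 1e-8) stop("composition must sum to 1")
  set.seed(deriveSeed(seed, "points", imageId))
  lab <- sample(types, n, replace = TRUE, prob = composition)
  truth <- list(process = process)
  if (process == "csr") {
    x <- stats::runif(n, 0, windowUm[1])
    y <- stats::runif(n, 0, windowUm[2])
  } else if (process == "clustered") {
    newParents <- function() cbind(stats::runif(nParents, 0, windowUm[1]),
                                   stats::runif(nParents, 0, windowUm[2]))
    parents <- if (sharedParents) newParents() else NULL
    perType <- lapply(types, function(t) {
      if (sharedParents) parents else newParents()
    })
    names(perType) <- types
    truth$parents <- perType
    pick <- vapply(lab, function(t) sample.int(nParents, 1L), 1L)
    px <- t(vapply(seq_len(n), function(i) perType[[lab[i]]][pick[i], ],
                   numeric(2)))
    x <- clamp(px[, 1] + stats::rnorm(n, sd = clusterSdUm), 0, windowUm[1])
    y <- clamp(px[, 2] + stats::rnorm(n, sd = clusterSdUm), 0, windowUm[2])
  } else {
    nT <- length(types)
    bandW <- (windowUm[1] - gapUm * (nT - 1)) / nT
    x0 <- (match(lab, types) - 1) * (bandW + gapUm)
    x <- x0 + stats::runif(n, 0, bandW)
    y <- stats::runif(n, 0, windowUm[2])
    truth$bandWidth <- bandW
    truth$gapUm <- gapUm
  }
  list(table = data.frame(image_id = imageId, group = group, x_um = x,
                          y_um = y, cell_type = lab),
       truth = truth)
}
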