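# Nuclear detections: overlap resolution between per-object masks,
# probability filtering, a threshold/watershed baseline segmenter, and
# label-map I/O for externally produced segmentations.

#' Resolve overlapping object masks into a label map
#'
#' Each pixel claimed by more than one object is assigned to the object
#' whose internal Euclidean distance map (distance to the object's own
#' background) is strictly greatest there; pixels that tie or lose
#' everywhere become background. Non-overlapping masks stack unchanged.
#'
#' @param masks list of binary matrices (one per object) sharing shape.
#' @param probabilities optional per-object probabilities (default 1).
#' @param pixelSize micrometres per pixel.
#' @return A \linkS4class{LabelMap}.
#' @export
resolveOverlaps <- function(masks, probabilities = NULL, pixelSize = 1) {
  if (!length(masks)) stop("at least one mask required")
  dims <- dim(masks[[1L]])
  n <- length(masks)
  best <- matrix(0, dims[1], dims[2])      # best distance seen
  second <- matrix(0, dims[1], dims[2])    # runner-up distance
  winner <- matrix(0L, dims[1], dims[2])
  for (k in seq_len(n)) {
    m <- masks[[k]] != 0
    if (!all(dim(m) == dims)) stop("masks must share shape")
    if (!any(m)) stop("mask ", k, " is empty")
    d <- as.matrix(EBImage::distmap(EBImage::Image(m * 1)))
    gt <- d > best
    second <- pmax(second, ifelse(gt, best, d))
    winner[gt] <- k
    best[gt] <- d[gt]
  }
  labels <- winner
  labels[best == 0 | best <= second] <- 0L  # strictly-greater rule: ties lose
  # keep ids dense: objects may lose all their pixels
  kept <- sort(unique(labels[labels > 0]))
  remap <- integer(n)
  remap[kept] <- seq_along(kept)
  labels[labels > 0] <- remap[labels[labels > 0]]
  p <- (probabilities %||% rep(1, n))[kept]
  LabelMap(labels, probabilities = p, pixelSize = pixelSize)
}

#' Filter objects by detection probability
#'
#' Removes objects whose detection probability is below \code{minP}
#' (strictly less than: boundary objects are kept) and re-densifies ids.
#' The old-to-new id mapping is attached as \code{attr(result, "idMap")}.
#'
#' @param lm a \linkS4class{LabelMap}.
#' @param minP probability threshold (default 0.5).
#' @return The filtered \linkS4class{LabelMap}.
#' @export
filterByProbability <- function(lm, minP = 0.5) {
  keep <- which(lm@probabilities >= minP)
  remap <- integer(length(lm@probabilities))
  remap[keep] <- seq_along(keep)
  labels <- lm@labels
  labels[labels > 0] <- remap[labels[labels > 0]]
  out <- LabelMap(labels, probabilities = lm@probabilities[keep],
                  pixelSize = lm@pixelSize)
  attr(out, "idMap") <- data.frame(old_id = keep, new_id = seq_along(keep))
  out
}

#' Remove objects smaller than a physical area
#'
#' Drops nuclei below \code{minAreaUm2} (fragment filter) and re-densifies
#' ids.
#'
#' @param lm a \linkS4class{LabelMap}.
#' @param minAreaUm2 minimum nucleus area in square micrometres.
#' @return The filtered \linkS4class{LabelMap}.
#' @export
filterBySize <- function(lm, minAreaUm2 = 4) {
  areas <- tabulate(lm@labels[lm@labels > 0], length(lm@probabilities))
  keep <- which(areas * lm@pixelSize^2 >= minAreaUm2)
  remap <- integer(length(lm@probabilities))
  remap[keep] <- seq_along(keep)
  labels <- lm@labels
  drop <- labels > 0 & remap[pmax(labels, 1L)] == 0L
  labels[drop] <- 0L
  labels[labels > 0] <- remap[labels[labels > 0]]
  LabelMap(labels, probabilities = lm@probabilities[keep],
           pixelSize = lm@pixelSize)
}

#' Threshold/watershed baseline nuclear segmentation
#'
#' Classical intensity-based segmentation used as the fallback when no
#' externally produced label map is supplied: Gaussian smoothing, Otsu
#' threshold, Euclidean distance transform, watershed. All object
#' probabilities are set to 1.
#'
#' @param dapi nuclear \linkS4class{ChannelImage}.
#' @param smoothingSigma Gaussian sigma in pixels (default 2).
#' @param minAreaPx remove objects smaller than this many pixels.
#' @return A \linkS4class{LabelMap}.
#' @export
baselineWatershedSegment <- function(dapi, smoothingSigma = 2, minAreaPx = 20) {
  img <- dapi@pixels / 65535
  if (max(img) == min(img)) {
    return(LabelMap(matrix(0L, nrow(img), ncol(img)),
                    pixelSize = dapi@pixelSize))
  }
  sm <- if (smoothingSigma > 0) {
    as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                                sigma = smoothingSigma)))
  } else img
  thr <- EBImage::otsu(EBImage::Image(sm), range = range(sm))
  bin <- sm > thr
  if (!any(bin)) {
    return(LabelMap(matrix(0L, nrow(img), ncol(img)),
                    pixelSize = dapi@pixelSize))
  }
  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labels <- as.matrix(EBImage::imageData(ws))
  if (minAreaPx > 0) {
    areas <- tabulate(labels[labels > 0])
    small <- which(areas < minAreaPx)
    labels[labels %in% small] <- 0L
  }
  ids <- sort(unique(labels[labels > 0]))
  remap <- integer(max(labels, 1L))
  remap[ids] <- seq_along(ids)
  labels[labels > 0] <- remap[labels[labels > 0]]
  LabelMap(labels, pixelSize = dapi@pixelSize)
}

#' Label-map I/O
#'
#' Label maps travel as integer TIFF plus a two-column probability table
#' (\code{id}, \code{p}) stored as CSV next to the image.
#'
#' @param lm a \linkS4class{LabelMap}.
#' @param path output TIFF path; probabilities go to \code{<path>.probs.csv}.
#' @return \code{path}, invisibly.
#' @export
writeLabelMap <- function(lm, path) {
  mx <- max(1L, max(lm@labels))
  if (mx > 65535) stop("more than 65535 objects cannot be stored as 16-bit")
  tiff::writeTIFF(lm@labels / 65535, path, bits.per.sample = 16L,
                  compression = "deflate")
  utils::write.csv(data.frame(id = seq_along(lm@probabilities),
                              p = lm@probabilities),
                   paste0(path, ".probs.csv"), row.names = FALSE)
  writeSidecar(path, list(format = "hyperplexR-labels",
                          pixel_size_um = lm@pixelSize,
                          n_objects = length(lm@probabilities)))
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
  sc <- readSidecar(path)
  labels <- round(tiff::readTIFF(path, as.is = TRUE))
  pf <- paste0(path, ".probs.csv")
  p <- if (file.exists(pf)) utils::read.csv(pf)$p else NULL
  LabelMap(labels, probabilities = p,
           pixelSize = (sc$pixel_size_um %||% 1))
}
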