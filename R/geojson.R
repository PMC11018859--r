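# Region masks as polygon GeoJSON (QuPath-style FeatureCollections carrying
# a classification name) and as single-channel TIFF.

#' Export a region mask as GeoJSON polygons
#'
#' Traces the outer contours of the mask's connected components and writes
#' them as a FeatureCollection of Polygons with a
#' \code{classification.name} property, in physical micrometre coordinates
#' (x = column, y = row).
#'
#' @param mask a \linkS4class{RegionMask}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRegionGeoJSON <- function(mask, path) {
  oc <- EBImage::ocontour(EBImage::bwlabel(EBImage::Image(mask@mask * 1)))
  ps <- mask@pixelSize
  features <- lapply(oc, function(ct) {
    # ocontour gives 0-based (row, col); GeoJSON wants closed x/y rings
    xy <- cbind(ct[, 2], ct[, 1]) * ps
    xy <- rbind(xy, xy[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(xy)),
                                                   function(i) xy[i, ]))),
         properties = list(classification = list(name = mask@label)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd scanline rasterisation of one polygon ring (micrometre coords)
# onto a logical matrix of shape dims with the given pixel size.
rasterizeRing <- function(ring, dims, pixelSize) {
  out <- matrix(FALSE, dims[1], dims[2])
  xs <- ring[, 1] / pixelSize  # col coordinate, 0-based
  ys <- ring[, 2] / pixelSize  # row coordinate
  n <- length(xs)
  for (r in seq_len(dims[1])) {
    yr <- r - 1
    crossings <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((ys[i] > yr) != (ys[j] > yr)) {
        crossings <- c(crossings,
                       xs[i] + (yr - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i]))
      }
      j <- i
    }
    crossings <- sort(crossings)
    for (k in seq_len(length(crossings) %/% 2)) {
      c0 <- max(1L, ceiling(crossings[2 * k - 1] + 1))
      c1 <- min(dims[2], floor(crossings[2 * k] + 1))
      if (c0 <= c1) out[r, c0:c1] <- TRUE
    }
  }
  out
}

#' Import a region mask from GeoJSON polygons
#'
#' Rasterises all Polygon features of a FeatureCollection (even-odd rule,
#' physical micrometre coordinates) into a binary mask. The region label is
#' taken from the first feature's \code{classification.name} unless given.
#'
#' @param path GeoJSON file.
#' @param dims output shape (rows, cols).
#' @param pixelSize micrometres per pixel.
#' @param label optional region name override.
#' @return A \linkS4class{RegionMask} with provenance \code{"imported"}.
#' @export
readRegionGeoJSON <- function(path, dims, pixelSize = 1, label = NULL) {
  gj <- jsonlite::read_json(path)
  mask <- matrix(FALSE, dims[1], dims[2])
  lab <- label
  for (f in gj$features) {
    if (is.null(lab)) lab <- f$properties$classification$name
    if (!identical(f$geometry$type, "Polygon")) next
    for (ringJson in f$geometry$coordinates) {
      ring <- do.call(rbind, lapply(ringJson, function(p) unlist(p)[1:2]))
      mask <- xor(mask, rasterizeRing(ring, dims, pixelSize))
    }
  }
  RegionMask(mask, label = lab %||% "region", provenance = "imported",
             pixelSize = pixelSize)
}

#' Region mask TIFF round-trip
#'
#' @param mask a \linkS4class{RegionMask}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMaskTIFF <- function(mask, path) {
  tiff::writeTIFF(mask@mask * 1, path, bits.per.sample = 8L,
                  compression = "deflate")
  writeSidecar(path, list(label = mask@label, pixel_size_um = mask@pixelSize))
  invisible(path)
}

#' @rdname writeMaskTIFF
#' @param label,pixelSize metadata used when no sidecar is found.
#' @export
readMaskTIFF <- function(path, label = NULL, pixelSize = NULL) {
  sc <- readSidecar(path)
  m <- tiff::readTIFF(path)
  RegionMask(m > 0.5, label = label %||% sc$label %||% "region",
             provenance = "imported",
             pixelSize = pixelSize %||% sc$pixel_size_um %||% 1)
}
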