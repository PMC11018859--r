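#' Construct a ChannelImage
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixelSize micrometres per pixel (isotropic).
#' @param channelName marker name.
#' @param roundIndex 1-based imaging round index.
#' @return A \linkS4class{ChannelImage}.
#' @export
ChannelImage <- function(pixels, pixelSize = 1, channelName = "unnamed",
                         roundIndex = 1L) {
  # storage mode (integer or double) is preserved: streaming large channels
  # must not force an extra full-size copy
  new("ChannelImage", pixels = as.matrix(pixels), pixelSize = pixelSize,
      channelName = channelName, roundIndex = as.integer(roundIndex))
}

#' Construct a RoundStack
#'
#' @param channels list of \linkS4class{ChannelImage} sharing shape and
#'   pixel size.
#' @param dapiIndex index (or name) of the nuclear reference channel.
#' @return A \linkS4class{RoundStack}.
#' @export
RoundStack <- function(channels, dapiIndex = 1L) {
  if (is.character(dapiIndex)) {
    dapiIndex <- match(dapiIndex, vapply(channels, function(ch) ch@channelName, ""))
    if (is.na(dapiIndex)) stop("DAPI channel name not found")
  }
  new("RoundStack", channels = channels, dapiIndex = as.integer(dapiIndex))
}

#' Construct a HyperplexStack
#'
#' @param channels list of aligned \linkS4class{ChannelImage}.
#' @param markerNames unique per-channel names; default taken from the
#'   channels, disambiguated with a round suffix where duplicated.
#' @return A \linkS4class{HyperplexStack}.
#' @export
HyperplexStack <- function(channels, markerNames = NULL) {
  if (is.null(markerNames)) {
    markerNames <- vapply(channels, function(ch) ch@channelName, "")
    dup <- duplicated(markerNames) | duplicated(markerNames, fromLast = TRUE)
    if (any(dup)) {
      rounds <- vapply(channels, function(ch) ch@roundIndex, 1L)
      markerNames[dup] <- paste0(markerNames[dup], "_r", rounds[dup])
    }
    if (anyDuplicated(markerNames)) {
      markerNames <- make.unique(markerNames, sep = "_")
    }
  }
  new("HyperplexStack", channels = channels, markerNames = markerNames,
      pixelSize = channels[[1L]]@pixelSize)
}

#' Construct a PlanarTransform
#'
#' @param matrix 2x3 matrix mapping moving (row, col) coordinates (0-based
#'   pixel units) into reference coordinates.
#' @param mode \code{"rigid"} or \code{"affine"}.
#' @param residual mean squared intensity difference of the fit, if known.
#' @return A \linkS4class{PlanarTransform}.
#' @export
PlanarTransform <- function(matrix = cbind(diag(2), c(0, 0)), mode = "rigid",
                            residual = NA_real_) {
  new("PlanarTransform", matrix = matrix, mode = mode, residual = residual)
}

#' Rigid transform from angle and shift
#'
#' Builds the rigid-body \linkS4class{PlanarTransform} that rotates by
#' \code{thetaDeg} degrees about the image center and then shifts by
#' \code{(dr, dc)} pixels.
#'
#' @param thetaDeg rotation in degrees (counter-clockwise in (row, col)).
#' @param dr,dc translation in pixels (rows, cols).
#' @param center rotation center (0-based pixel coords), default the image
#'   center of a \code{dim}-shaped image.
#' @param dim image shape used to derive the default center.
#' @return A \linkS4class{PlanarTransform} of mode \code{"rigid"}.
#' @export
rigidTransform <- function(thetaDeg = 0, dr = 0, dc = 0, center = NULL,
                           dim = NULL) {
  if (is.null(center)) {
    center <- if (is.null(dim)) c(0, 0) else (dim - 1) / 2
  }
  th <- thetaDeg * pi / 180
  A <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  b <- center - A %*% center + c(dr, dc)
  PlanarTransform(cbind(A, b), mode = "rigid")
}

#' Invert a planar transform
#'
#' @param t a \linkS4class{PlanarTransform}.
#' @return The inverse \linkS4class{PlanarTransform}.
#' @export
invertTransform <- function(t) {
  A <- t@matrix[, 1:2, drop = FALSE]
  b <- t@matrix[, 3]
  Ai <- solve(A)
  PlanarTransform(cbind(Ai, -Ai %*% b), mode = t@mode)
}

#' Apply a planar transform to point coordinates
#'
#' @param t a \linkS4class{PlanarTransform}.
#' @param points n x 2 matrix of (row, col) coordinates, 0-based pixel units.
#' @return n x 2 matrix of mapped coordinates.
#' @export
transformPoints <- function(t, points) {
  points <- rbind(points)
  out <- points %*% t(t@matrix[, 1:2]) +
    matrix(t@matrix[, 3], nrow(points), 2, byrow = TRUE)
  colnames(out) <- c("row", "col")
  out
}

#' Construct a LabelMap
#'
#' @param labels integer matrix (0 = background, k = object k; ids dense
#'   from 1).
#' @param probabilities per-object detection probabilities; default 1.
#' @param pixelSize micrometres per pixel.
#' @return A \linkS4class{LabelMap}.
#' @export
LabelMap <- function(labels, probabilities = NULL, pixelSize = 1) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  n <- max(0L, max(labels))
  if (is.null(probabilities)) probabilities <- rep(1, n)
  new("LabelMap", labels = labels, probabilities = as.numeric(probabilities),
      pixelSize = pixelSize)
}

#' Construct a RegionMask
#'
#' @param mask logical matrix.
#' @param label region name.
#' @param provenance "classifier", "imported" or "derived".
#' @param pixelSize micrometres per pixel.
#' @return A \linkS4class{RegionMask}.
#' @export
RegionMask <- function(mask, label, provenance = "imported", pixelSize = 1) {
  storage.mode(mask) <- "logical"
  new("RegionMask", mask = mask, label = label, provenance = provenance,
      pixelSize = pixelSize)
}

#' Construct a RegionSet
#'
#' @param masks list of \linkS4class{RegionMask}; names are taken from the
#'   mask labels.
#' @return A \linkS4class{RegionSet}.
#' @export
RegionSet <- function(masks = list()) {
  names(masks) <- vapply(masks, function(m) m@label, "")
  new("RegionSet", masks = masks)
}

#' @rdname RegionSet
#' @param x a RegionSet.
#' @param label region label to extract.
#' @export
getRegion <- function(x, label) {
  if (!label %in% names(x@masks)) stop("no region named '", label, "'")
  x@masks[[label]]
}

#' @rdname RegionSet
#' @param mask a \linkS4class{RegionMask} to add or replace.
#' @export
setRegion <- function(x, mask) {
  x@masks[[mask@label]] <- mask
  validObject(x)
  x
}

#' @rdname RegionSet
#' @export
regionNames <- function(x) names(x@masks)
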