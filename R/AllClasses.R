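#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib hyperplexR, .registration = TRUE
NULL

#' Single-channel image with physical metadata
#'
#' One fluorescence channel of one imaging round: a non-negative intensity
#' matrix (rows = y, columns = x) with isotropic pixel size in micrometres,
#' a marker name and the index of the imaging round it came from. Physical
#' coordinates are pixel-center: a pixel at matrix position (i, j) sits at
#' ((i - 1) * pixelSize, (j - 1) * pixelSize) micrometres.
#'
#' @slot pixels numeric matrix of finite, non-negative intensities
#'   (16-bit range by convention, stored as doubles).
#' @slot pixelSize micrometres per pixel (isotropic, > 0).
#' @slot channelName marker identifier, e.g. \code{"DAPI"} or \code{"GFAP"}.
#' @slot roundIndex imaging round the channel belongs to (1-based).
#' @exportClass ChannelImage
setClass("ChannelImage",
  representation(
    pixels      = "matrix",
    pixelSize   = "numeric",
    channelName = "character",
    roundIndex  = "integer"
  ),
  prototype(pixelSize = 1, channelName = "unnamed", roundIndex = 1L)
)

setValidity("ChannelImage", function(object) {
  msg <- NULL
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  else {
    # range() avoids full-size logical temporaries on whole-slide channels
    rng <- suppressWarnings(range(object@pixels))
    if (anyNA(rng) || any(!is.finite(rng))) msg <- c(msg, "pixels must be finite")
    else if (rng[1] < 0) msg <- c(msg, "pixels must be >= 0")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) {
    msg <- c(msg, "pixelSize must be a single positive number")
  }
  if (length(object@channelName) != 1L || !nzchar(object@channelName)) {
    msg <- c(msg, "channelName must be a non-empty string")
  }
  if (length(object@roundIndex) != 1L || is.na(object@roundIndex) ||
      object@roundIndex < 0L) {
    msg <- c(msg, "roundIndex must be a single non-negative integer")
  }
  if (is.null(msg)) TRUE else msg
})

#' Multi-channel stack of one imaging round
#'
#' Ordered channels sharing shape and pixel size, with the index of the
#' nuclear (DAPI) reference channel used for registration.
#'
#' @slot channels list of \linkS4class{ChannelImage}, all the same shape.
#' @slot dapiIndex index of the single DAPI channel within \code{channels}.
#' @exportClass RoundStack
setClass("RoundStack",
  representation(channels = "list", dapiIndex = "integer")
)

setValidity("RoundStack", function(object) {
  msg <- NULL
  if (length(object@channels) < 1L) msg <- c(msg, "at least one channel required")
  if (!all(vapply(object@channels, is, TRUE, "ChannelImage"))) {
    return("channels must all be ChannelImage objects")
  }
  dims <- vapply(object@channels, function(ch) dim(ch@pixels), integer(2))
  if (length(object@channels) > 1L && !all(dims == dims[, 1L])) {
    msg <- c(msg, "all channels must share the same shape")
  }
  ps <- vapply(object@channels, function(ch) ch@pixelSize, 0)
  if (max(ps) - min(ps) > 1e-9) msg <- c(msg, "all channels must share pixelSize")
  if (length(object@dapiIndex) != 1L || is.na(object@dapiIndex) ||
      object@dapiIndex < 1L || object@dapiIndex > length(object@channels)) {
    msg <- c(msg, "dapiIndex out of range")
  }
  if (is.null(msg)) TRUE else msg
})

#' Aligned multi-round (hyperplexed) image stack
#'
#' The concatenation of all imaging rounds after registration into the
#' round-1 reference frame: one \linkS4class{ChannelImage} per retained
#' channel, with unique marker names and a shared pixel size.
#'
#' @slot channels list of aligned \linkS4class{ChannelImage}.
#' @slot markerNames character vector, one unique name per channel.
#' @slot pixelSize micrometres per pixel.
#' @exportClass HyperplexStack
setClass("HyperplexStack",
  representation(channels = "list", markerNames = "character",
                 pixelSize = "numeric")
)

setValidity("HyperplexStack", function(object) {
  msg <- NULL
  if (length(object@channels) != length(object@markerNames)) {
    msg <- c(msg, "one marker name per channel required")
  }
  if (anyDuplicated(object@markerNames)) {
    msg <- c(msg, "marker names must be unique")
  }
  if (!all(vapply(object@channels, is, TRUE, "ChannelImage"))) {
    return("channels must all be ChannelImage objects")
  }
  if (length(object@channels) > 1L) {
    dims <- vapply(object@channels, function(ch) dim(ch@pixels), integer(2))
    if (!all(dims == dims[, 1L])) msg <- c(msg, "channels must share shape")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0) {
    msg <- c(msg, "pixelSize must be a single positive number")
  }
  if (is.null(msg)) TRUE else msg
})

#' Planar rigid-body or affine transform
#'
#' A 2x3 matrix mapping moving-image coordinates (0-based pixel units,
#' (row, col)) into reference coordinates: ref = A %*% mov + b, with
#' \code{matrix = cbind(A, b)}. Rigid transforms have an orthonormal linear
#' part with determinant +1.
#'
#' @slot mode \code{"rigid"} or \code{"affine"}.
#' @slot matrix 2x3 numeric matrix.
#' @slot residual final mean squared intensity difference of the fit
#'   (NA when the transform was constructed, not estimated).
#' @exportClass PlanarTransform
setClass("PlanarTransform",
  representation(mode = "character", matrix = "matrix", residual = "numeric"),
  prototype(mode = "rigid", residual = NA_real_)
)

setValidity("PlanarTransform", function(object) {
  msg <- NULL
  if (!object@mode %in% c("rigid", "affine")) {
    msg <- c(msg, "mode must be 'rigid' or 'affine'")
  }
  if (!all(dim(object@matrix) == c(2L, 3L))) {
    return("matrix must be 2x3")
  }
  A <- object@matrix[, 1:2]
  if (abs(det(A)) < 1e-12) msg <- c(msg, "transform must be invertible")
  if (object@mode == "rigid") {
    if (max(abs(crossprod(A) - diag(2))) > 1e-6 || det(A) < 0) {
      msg <- c(msg, "rigid transform must have orthonormal linear part with det +1")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Integer label map of segmented objects
#'
#' Nuclear (or cell) segmentation encoded as an integer matrix: 0 is
#' background, k marks pixels of object k. Object ids are dense from 1 and
#' each carries a detection probability in [0, 1].
#'
#' @slot labels integer matrix of object labels.
#' @slot probabilities per-object detection score, length = number of objects.
#' @slot pixelSize micrometres per pixel.
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "matrix", probabilities = "numeric",
                 pixelSize = "numeric"),
  prototype(pixelSize = 1)
)

setValidity("LabelMap", function(object) {
  msg <- NULL
  labs <- object@labels
  if (any(labs < 0)) msg <- c(msg, "labels must be >= 0")
  n <- max(0L, suppressWarnings(max(labs)))
  ids <- sort(unique(labs[labs > 0]))
  if (length(ids) && !identical(as.integer(ids), seq_len(n))) {
    msg <- c(msg, "object ids must be dense from 1")
  }
  if (length(object@probabilities) != n) {
    msg <- c(msg, "probabilities length must equal the object count")
  } else if (n > 0 && (any(object@probabilities < 0) ||
                       any(object@probabilities > 1))) {
    msg <- c(msg, "probabilities must lie in [0, 1]")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0) {
    msg <- c(msg, "pixelSize must be a single positive number")
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-cell measurement zones
#'
#' The four measurement zones of each segmented cell, encoded as two integer
#' label maps sharing the frame of the nuclear segmentation: nucleus labels
#' and (expanded, pairwise-disjoint) whole-cell labels. Cytoplasm and
#' membrane are derived: cytoplasm = cell minus nucleus; membrane = the
#' 1-pixel boundary ring of the cell mask (configurable width).
#'
#' @slot nucleusLabels integer matrix of nucleus labels.
#' @slot cellLabels integer matrix of whole-cell labels (nucleus included).
#' @slot membraneWidth width of the membrane ring in pixels.
#' @slot probabilities per-object detection probabilities carried over from
#'   the nuclear \linkS4class{LabelMap}.
#' @slot pixelSize micrometres per pixel.
#' @exportClass CellZones
setClass("CellZones",
  representation(nucleusLabels = "matrix", cellLabels = "matrix",
                 membraneWidth = "integer", probabilities = "numeric",
                 pixelSize = "numeric"),
  prototype(membraneWidth = 1L, pixelSize = 1)
)

setValidity("CellZones", function(object) {
  msg <- NULL
  if (!all(dim(object@nucleusLabels) == dim(object@cellLabels))) {
    return("nucleus and cell label maps must share shape")
  }
  inside <- object@nucleusLabels > 0
  if (any(object@cellLabels[inside] != object@nucleusLabels[inside])) {
    msg <- c(msg, "every nucleus pixel must belong to its own cell")
  }
  if (object@membraneWidth < 1L) msg <- c(msg, "membraneWidth must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Named binary region mask
#'
#' @slot mask logical matrix in the reference frame.
#' @slot label region name (e.g. "tumor", "vessel").
#' @slot provenance one of "classifier", "imported", "derived".
#' @slot pixelSize micrometres per pixel.
#' @exportClass RegionMask
setClass("RegionMask",
  representation(mask = "matrix", label = "character",
                 provenance = "character", pixelSize = "numeric"),
  prototype(provenance = "imported", pixelSize = 1)
)

setValidity("RegionMask", function(object) {
  msg <- NULL
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!object@provenance %in% c("classifier", "imported", "derived")) {
    msg <- c(msg, "provenance must be classifier/imported/derived")
  }
  if (length(object@label) != 1L || !nzchar(object@label)) {
    msg <- c(msg, "label must be a non-empty string")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0) {
    msg <- c(msg, "pixelSize must be positive")
  }
  if (is.null(msg)) TRUE else msg
})

#' Collection of region masks
#'
#' Named collection of \linkS4class{RegionMask} objects sharing one frame.
#' Conventional base labels are lesion, tumor, brain, vessel, ecm and
#' excluded; derived labels (border, perivascular, lesion_context) are
#' reproducible functions of the base masks.
#'
#' @slot masks named list of \linkS4class{RegionMask}.
#' @exportClass RegionSet
setClass("RegionSet", representation(masks = "list"))

setValidity("RegionSet", function(object) {
  msg <- NULL
  if (!all(vapply(object@masks, is, TRUE, "RegionMask"))) {
    return("masks must all be RegionMask objects")
  }
  labs <- vapply(object@masks, function(m) m@label, "")
  if (anyDuplicated(labs)) msg <- c(msg, "region labels must be unique")
  if (!identical(names(object@masks), unname(labs))) {
    msg <- c(msg, "list names must equal mask labels")
  }
  if (length(object@masks) > 1L) {
    dims <- vapply(object@masks, function(m) dim(m@mask), integer(2))
    if (!all(dims == dims[, 1L])) msg <- c(msg, "masks must share shape")
  }
  if (is.null(msg)) TRUE else msg
})

#' Trained self-organizing map
#'
#' Codebook of a rectangular-grid SOM trained on min-max scaled marker
#' intensities, together with the training metadata needed to reproduce it.
#'
#' @slot grid integer (rows, cols) of the node grid; 10 x 10 by default.
#' @slot codebook numeric matrix, one row per node, columns = markers.
#' @slot seed RNG seed used for initialisation.
#' @slot epochs number of batch training sweeps.
#' @slot sigma neighborhood radius schedule endpoints (start, end).
#' @slot quantError final mean quantization error.
#' @exportClass SOMModel
setClass("SOMModel",
  representation(grid = "integer", codebook = "matrix", seed = "integer",
                 epochs = "integer", sigma = "numeric", quantError = "numeric")
)

setValidity("SOMModel", function(object) {
  msg <- NULL
  if (length(object@grid) != 2L || any(object@grid < 1L)) {
    msg <- c(msg, "grid must be two positive integers")
  }
  if (nrow(object@codebook) != prod(object@grid)) {
    msg <- c(msg, "codebook must have one row per grid node")
  }
  if (length(object@sigma) != 2L || any(object@sigma <= 0)) {
    msg <- c(msg, "sigma must be (start, end), both > 0")
  }
  if (is.null(msg)) TRUE else msg
})
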