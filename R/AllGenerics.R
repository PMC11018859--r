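#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("imageData", function(x, ...) standardGeneric("imageData"))

#' Accessors for image containers
#'
#' \code{pixelSize} returns the pixel edge length in micrometres;
#' \code{channelNames} the marker names; \code{nChannels} the channel count;
#' \code{imageData} the raw intensity matrix of a channel.
#'
#' @param x a \linkS4class{ChannelImage}, \linkS4class{RoundStack},
#'   \linkS4class{HyperplexStack}, \linkS4class{LabelMap} or
#'   \linkS4class{RegionMask}.
#' @param ... for \code{imageData} on multi-channel containers, the channel
#'   index or name to extract.
#' @return See the individual descriptions.
#' @name accessors
NULL

setMethod("pixelSize", "ChannelImage", function(x) x@pixelSize)
setMethod("pixelSize", "RoundStack", function(x) x@channels[[1L]]@pixelSize)
setMethod("pixelSize", "HyperplexStack", function(x) x@pixelSize)
setMethod("pixelSize", "LabelMap", function(x) x@pixelSize)
setMethod("pixelSize", "RegionMask", function(x) x@pixelSize)

setMethod("channelNames", "RoundStack",
          function(x) vapply(x@channels, function(ch) ch@channelName, ""))
setMethod("channelNames", "HyperplexStack", function(x) x@markerNames)
setMethod("channelNames", "ChannelImage", function(x) x@channelName)

setMethod("nChannels", "RoundStack", function(x) length(x@channels))
setMethod("nChannels", "HyperplexStack", function(x) length(x@channels))

setMethod("imageData", "ChannelImage", function(x, ...) x@pixels)
setMethod("imageData", "RoundStack", function(x, i) {
  if (is.character(i)) i <- match(i, channelNames(x))
  x@channels[[i]]@pixels
})
setMethod("imageData", "HyperplexStack", function(x, i) {
  if (is.character(i)) i <- match(i, x@markerNames)
  x@channels[[i]]@pixels
})

#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, i) standardGeneric("getChannel"))
setMethod("getChannel", "RoundStack", function(x, i) {
  if (is.character(i)) i <- match(i, channelNames(x))
  x@channels[[i]]
})
setMethod("getChannel", "HyperplexStack", function(x, i) {
  if (is.character(i)) i <- match(i, x@markerNames)
  x@channels[[i]]
})

setMethod("show", "ChannelImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ChannelImage '%s' (round %d): %d x %d px, %.4g um/px\n",
              object@channelName, object@roundIndex, d[1], d[2],
              object@pixelSize))
})

setMethod("show", "RoundStack", function(object) {
  d <- dim(object@channels[[1L]]@pixels)
  cat(sprintf("RoundStack: %d channels, %d x %d px, %.4g um/px, DAPI = '%s'\n",
              length(object@channels), d[1], d[2], pixelSize(object),
              channelNames(object)[object@dapiIndex]))
})

setMethod("show", "HyperplexStack", function(object) {
  d <- dim(object@channels[[1L]]@pixels)
  cat(sprintf("HyperplexStack: %d channels, %d x %d px, %.4g um/px\n",
              length(object@channels), d[1], d[2], object@pixelSize))
  cat("  markers:", paste(utils::head(object@markerNames, 8), collapse = ", "),
      if (length(object@markerNames) > 8) "..." else "", "\n")
})

setMethod("show", "PlanarTransform", function(object) {
  cat(sprintf("PlanarTransform (%s), residual = %.6g\n", object@mode,
              object@residual))
  print(round(object@matrix, 6))
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap: %d objects, %d x %d px, %.4g um/px\n",
              length(object@probabilities), nrow(object@labels),
              ncol(object@labels), object@pixelSize))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask '%s' (%s): %d x %d px, %.1f%% foreground\n",
              object@label, object@provenance, nrow(object@mask),
              ncol(object@mask), 100 * mean(object@mask)))
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet:", paste(names(object@masks), collapse = ", "), "\n")
})

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %d x %d grid, %d markers, quantization error %.4g\n",
              object@grid[1], object@grid[2], ncol(object@codebook),
              object@quantError))
})
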