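# Multi-channel whole-slide image I/O with a one-channel-resident streaming
# contract. Files are multi-page TIFFs (16-bit, lossless compression), pages
# ordered level-major (all channels of pyramid level 0 first). Channel names,
# pixel size and the pyramid layout travel in a JSON sidecar written next to
# the image; on read, metadata is resolved from an explicit override, the
# sidecar, OME-XML found in the ImageDescription tag, or TIFF resolution
# tags, in that order.

sidecarPath <- function(path) paste0(path, ".json")

writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA)
}

readSidecar <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

# Parse channel names / pixel size out of an OME-XML ImageDescription.
parseOMEDescription <- function(desc) {
  out <- list(channel_names = NULL, pixel_size_um = NULL)
  if (is.null(desc) || !nzchar(desc) || !grepl("<", desc, fixed = TRUE)) {
    return(out)
  }
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(out)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (!inherits(px, "xml_missing")) {
    psx <- xml2::xml_attr(px, "PhysicalSizeX")
    if (!is.na(psx)) out$pixel_size_um <- as.numeric(psx)
    chs <- xml2::xml_find_all(px, ".//*[local-name()='Channel']")
    if (length(chs)) {
      nm <- xml2::xml_attr(chs, "Name")
      if (!all(is.na(nm))) out$channel_names <- nm
    }
  }
  out
}

# Pixel size from TIFF resolution tags (pixels per unit; unit inch or cm).
pixelSizeFromTags <- function(info) {
  xres <- attr(info, "x.resolution")
  unit <- attr(info, "resolution.unit") %||% "inch"
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  per_um <- switch(unit, inch = xres / 25400, cm = xres / 1e4, NULL)
  if (is.null(per_um)) return(NULL)
  1 / per_um
}

resolveMeta <- function(path, nPages) {
  sc <- readSidecar(path)
  if (!is.null(sc)) {
    sc$n_levels <- sc$n_levels %||% 1L
    sc$n_channels <- sc$n_channels %||% nPages
    return(sc)
  }
  first <- tiff::readTIFF(path, all = 1, info = TRUE)
  if (is.list(first)) first <- first[[1L]]
  ome <- parseOMEDescription(attr(first, "description"))
  list(n_channels = nPages, n_levels = 1L,
       channel_names = ome$channel_names,
       pixel_size_um = ome$pixel_size_um %||% pixelSizeFromTags(first))
}

countPages <- function(path) {
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (is.data.frame(info)) nrow(info) else length(info)
}

readPage <- function(path, page) {
  x <- tiff::readTIFF(path, all = page, as.is = TRUE)
  if (is.list(x)) x <- x[[1L]]
  x  # integer storage kept: one decoded channel, no extra full-size copy
}

#' Read one imaging round from a multi-channel TIFF
#'
#' Reads all full-resolution channels of a round and resolves channel names
#' and pixel size from file metadata (JSON sidecar, OME-XML description or
#' TIFF resolution tags), with explicit arguments winning on conflict.
#'
#' @param path multi-page TIFF or OME-TIFF.
#' @param channelNames optional character vector naming the channels; must
#'   match the channel count when supplied.
#' @param pixelSizeOverride optional pixel size in micrometres, overriding
#'   file metadata.
#' @param dapiChannel name (or index) of the nuclear reference channel.
#' @param roundIndex 1-based round index stored on each channel.
#' @return A \linkS4class{RoundStack}.
#' @export
readRound <- function(path, channelNames = NULL, pixelSizeOverride = NULL,
                      dapiChannel = "DAPI", roundIndex = 1L) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  nPages <- countPages(path)
  meta <- resolveMeta(path, nPages)
  nCh <- meta$n_channels
  if (!is.null(channelNames) && length(channelNames) != nCh) {
    stop(sprintf("%d channel names supplied for %d channels",
                 length(channelNames), nCh))
  }
  nm <- channelNames %||% meta$channel_names %||% paste0("ch", seq_len(nCh))
  ps <- pixelSizeOverride %||% meta$pixel_size_um
  if (is.null(ps)) stop("pixel size not present in metadata and no override given")
  channels <- lapply(seq_len(nCh), function(i) {
    ChannelImage(readPage(path, i), pixelSize = ps, channelName = nm[i],
                 roundIndex = roundIndex)
  })
  RoundStack(channels, dapiIndex = dapiChannel)
}

#' Stream a single channel from disk
#'
#' Decodes only the requested full-resolution channel, so the peak working
#' set is bounded by one channel plus constant overhead regardless of the
#' stack's channel count.
#'
#' @param path multi-page TIFF written by \code{\link{writeHyperplex}} (or
#'   any multi-page TIFF with one channel per page).
#' @param channelIndex 1-based channel index at full resolution.
#' @param pixelSizeOverride optional pixel size in micrometres.
#' @return A \linkS4class{ChannelImage}.
#' @export
streamChannel <- function(path, channelIndex, pixelSizeOverride = NULL) {
  meta <- readSidecar(path)
  nCh <- if (!is.null(meta)) meta$n_channels else countPages(path)
  if (channelIndex < 1L || channelIndex > nCh) {
    stop("channel index ", channelIndex, " out of range (1..", nCh, ")")
  }
  nm <- if (!is.null(meta) && !is.null(meta$channel_names)) {
    meta$channel_names[channelIndex]
  } else paste0("ch", channelIndex)
  ps <- pixelSizeOverride %||% (if (!is.null(meta)) meta$pixel_size_um) %||% 1
  ChannelImage(readPage(path, channelIndex), pixelSize = ps, channelName = nm)
}

#' Write an aligned hyperplex stack as a pyramidal multi-page TIFF
#'
#' All channels are stored losslessly at full resolution, followed by
#' 2x-downsampled pyramid levels (level k has shape \code{ceiling(dim/2^k)}).
#' Pixel size, marker names and the pyramid layout are propagated via a JSON
#' sidecar so that \code{\link{readHyperplex}} and \code{\link{readRound}}
#' recover them.
#'
#' @param stack a \linkS4class{HyperplexStack} (or \linkS4class{RoundStack}).
#' @param path output file.
#' @param pyramidLevels number of resolution levels including level 0 (>= 1).
#' @param tileSize nominal tile edge recorded in the metadata (the encoder
#'   writes strips; the value documents the intended chunking).
#' @param compression lossless codec: "deflate", "LZW" or "none".
#' @return \code{path}, invisibly.
#' @export
writeHyperplex <- function(stack, path, pyramidLevels = 1L, tileSize = 512L,
                           compression = "deflate") {
  if (pyramidLevels < 1L) stop("pyramidLevels must be >= 1")
  if (tileSize < 16L) stop("invalid tile size")
  if (is(stack, "RoundStack")) {
    stack <- HyperplexStack(stack@channels)
  }
  mats <- lapply(stack@channels, function(ch) ch@pixels)
  if (max(vapply(mats, max, 0)) > 65535) {
    stop("pixel values exceed the 16-bit range")
  }
  pages <- list()
  lvl <- mats
  for (k in seq_len(pyramidLevels)) {
    pages <- c(pages, lapply(lvl, function(m) m / 65535))
    if (k < pyramidLevels) lvl <- lapply(lvl, halveImage)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = compression,
                  reduce = FALSE)
  writeSidecar(path, list(
    format = "hyperplexR-pyramid",
    n_channels = length(mats),
    n_levels = pyramidLevels,
    tile_size = tileSize,
    pixel_size_um = stack@pixelSize,
    channel_names = as.list(stack@markerNames),
    shape_level0 = dim(mats[[1L]])
  ))
  invisible(path)
}

#' Read a hyperplex stack written by \code{writeHyperplex}
#'
#' @param path file written by \code{\link{writeHyperplex}}.
#' @param level pyramid level to read (0 = full resolution).
#' @return A \linkS4class{HyperplexStack}.
#' @export
readHyperplex <- function(path, level = 0L) {
  meta <- readSidecar(path)
  if (is.null(meta)) {
    meta <- resolveMeta(path, countPages(path))
  }
  if (level < 0L || level >= meta$n_levels) {
    stop("pyramid level ", level, " out of range")
  }
  nCh <- meta$n_channels
  nm <- unlist(meta$channel_names) %||% paste0("ch", seq_len(nCh))
  ps <- meta$pixel_size_um %||% 1
  pages <- level * nCh + seq_len(nCh)
  channels <- lapply(seq_len(nCh), function(i) {
    ChannelImage(readPage(path, pages[i]), pixelSize = ps * 2^level,
                 channelName = nm[i])
  })
  HyperplexStack(channels, markerNames = nm)
}

#' Write a single imaging round to disk
#'
#' Convenience wrapper storing one \linkS4class{RoundStack} as a flat
#' (single-level) multi-page TIFF with sidecar metadata.
#'
#' @param round a \linkS4class{RoundStack}.
#' @param path output file.
#' @param compression lossless codec.
#' @return \code{path}, invisibly.
#' @export
writeRound <- function(round, path, compression = "deflate") {
  mats <- lapply(round@channels, function(ch) ch@pixels / 65535)
  tiff::writeTIFF(mats, path, bits.per.sample = 16L, compression = compression,
                  reduce = FALSE)
  writeSidecar(path, list(
    format = "hyperplexR-round",
    n_channels = length(mats),
    n_levels = 1L,
    pixel_size_um = pixelSize(round),
    channel_names = as.list(channelNames(round)),
    dapi_index = round@dapiIndex,
    shape_level0 = dim(round@channels[[1L]]@pixels)
  ))
  invisible(path)
}
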