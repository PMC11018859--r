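# End-to-end alignment of a cyclic-IF experiment: round 1 DAPI is the
# reference; every later round (and the optional pre-antibody
# autofluorescence round) estimates its transform on DAPI and warps all of
# its channels; marker channels then have the aligned autofluorescence
# image subtracted pixel-by-pixel, except channels on the skip list (e.g.
# endogenous GFP) and DAPI itself, which carries true signal in the
# autofluorescence round.

resolveAfIndex <- function(chName, chPos, afRound, afMap) {
  afNames <- channelNames(afRound)
  if (!is.null(afMap)) {
    if (!chName %in% names(afMap)) {
      stop("afMap does not cover channel '", chName, "'")
    }
    idx <- match(afMap[[chName]], afNames)
    if (is.na(idx)) stop("afMap target '", afMap[[chName]], "' not in AF round")
    return(idx)
  }
  idx <- match(chName, afNames)
  if (!is.na(idx)) return(idx)
  if (chPos <= length(afNames)) return(chPos)
  stop("no autofluorescence channel for '", chName, "'")
}

#' Align all rounds of a cyclic-IF experiment into one stack
#'
#' Registers every round to the round-1 DAPI reference, propagates each
#' round's transform to all of its channels, optionally subtracts the
#' aligned autofluorescence round pixel-by-pixel, and concatenates the
#' result into a \linkS4class{HyperplexStack} with propagated metadata.
#' The estimated per-round transforms are attached as
#' \code{attr(result, "transforms")}.
#'
#' @param rounds list of \linkS4class{RoundStack}s sharing shape and pixel
#'   size; the first round defines the reference frame.
#' @param afRound optional pre-antibody autofluorescence
#'   \linkS4class{RoundStack}, aligned like any other round.
#' @param afMap optional named list mapping channel names to the name of
#'   their matched autofluorescence channel; by default channels match by
#'   name, falling back to position (the excitation/emission filter slot).
#' @param skipAfChannels channel names exempt from autofluorescence
#'   subtraction (endogenous fluorophores such as GFP). DAPI channels are
#'   always exempt.
#' @param mode \code{"rigid"} or \code{"affine"} registration.
#' @param afScale multiplier on the autofluorescence image.
#' @param keepDapi \code{"first"} (default) keeps only the round-1 DAPI in
#'   the output; \code{"all"} keeps every round's DAPI.
#' @param force if TRUE, a round whose registration fails is passed through
#'   with the identity transform and a warning instead of aborting.
#' @return A \linkS4class{HyperplexStack}.
#' @export
alignExperiment <- function(rounds, afRound = NULL, afMap = NULL,
                            skipAfChannels = character(),
                            mode = c("rigid", "affine"), afScale = 1.0,
                            keepDapi = c("first", "all"), force = FALSE) {
  mode <- match.arg(mode)
  keepDapi <- match.arg(keepDapi)
  if (length(rounds) < 1L) stop("at least one round required")
  refDims <- dim(rounds[[1L]]@channels[[1L]]@pixels)
  ps <- pixelSize(rounds[[1L]])
  for (rs in c(rounds, if (!is.null(afRound)) list(afRound))) {
    if (!all(dim(rs@channels[[1L]]@pixels) == refDims)) {
      stop("all rounds must share the reference shape")
    }
    if (abs(pixelSize(rs) - ps) > 1e-9) stop("all rounds must share pixel size")
  }
  refDapi <- getChannel(rounds[[1L]], rounds[[1L]]@dapiIndex)

  estimateOrIdentity <- function(movDapi, what) {
    tryCatch(
      estimateTransform(refDapi, movDapi, mode = mode),
      error = function(e) {
        if (!force) stop("registration of ", what, " failed: ",
                         conditionMessage(e))
        warning(what, " passed through unregistered: ", conditionMessage(e))
        PlanarTransform(mode = mode)
      }
    )
  }

  afAligned <- NULL
  transforms <- list()
  if (!is.null(afRound)) {
    tAf <- estimateOrIdentity(getChannel(afRound, afRound@dapiIndex),
                              "autofluorescence round")
    afAligned <- lapply(afRound@channels, applyTransform, t = tAf)
    names(afAligned) <- channelNames(afRound)
    transforms$af <- tAf
  }

  out <- list()
  for (k in seq_along(rounds)) {
    rs <- rounds[[k]]
    t <- if (k == 1L) PlanarTransform(mode = mode) else {
      estimateOrIdentity(getChannel(rs, rs@dapiIndex), paste("round", k))
    }
    transforms[[paste0("round", k)]] <- t
    for (j in seq_along(rs@channels)) {
      isDapi <- j == rs@dapiIndex
      if (isDapi && keepDapi == "first" && k > 1L) next
      ch <- rs@channels[[j]]
      warped <- if (k == 1L) ch else applyTransform(ch, t)
      warped@roundIndex <- as.integer(k)
      if (!is.null(afAligned) && !isDapi &&
          !(ch@channelName %in% skipAfChannels)) {
        afIdx <- resolveAfIndex(ch@channelName, j, afRound, afMap)
        warped <- subtractAutofluorescence(warped, afAligned[[afIdx]],
                                           scale = afScale)
      }
      out[[length(out) + 1L]] <- warped
    }
  }
  stack <- HyperplexStack(out)
  attr(stack, "transforms") <- transforms
  stack
}

#' Streaming alignment of rounds stored on disk
#'
#' Disk-to-disk variant of \code{\link{alignExperiment}} honoring the
#' one-channel-resident memory contract end to end: per round, only the
#' DAPI channel is loaded to estimate the transform, then each channel is
#' streamed, warped, autofluorescence-subtracted and written to its own
#' single-channel TIFF before the next is touched. The output directory
#' holds one file per aligned channel plus a JSON manifest (channel order,
#' pixel size, transforms); \code{readAlignedDir} reassembles a
#' \linkS4class{HyperplexStack} from it (which, by nature, loads all
#' channels).
#'
#' @param roundPaths per-round TIFF files (see \code{\link{writeRound}});
#'   the first is the reference round.
#' @param outDir output directory, created if needed.
#' @param afPath optional autofluorescence round file.
#' @param dapiChannel DAPI channel name.
#' @param skipAfChannels channels exempt from autofluorescence subtraction.
#' @param mode \code{"rigid"} or \code{"affine"}.
#' @param afScale multiplier on the autofluorescence image.
#' @param keepDapi \code{"first"} or \code{"all"}.
#' @return \code{outDir}, invisibly.
#' @export
alignExperimentDir <- function(roundPaths, outDir, afPath = NULL,
                               dapiChannel = "DAPI",
                               skipAfChannels = character(),
                               mode = c("rigid", "affine"), afScale = 1.0,
                               keepDapi = c("first", "all")) {
  mode <- match.arg(mode)
  keepDapi <- match.arg(keepDapi)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  chanNamesOf <- function(path) unlist(readSidecar(path)$channel_names)
  dapiIndexOf <- function(path) {
    idx <- match(dapiChannel, chanNamesOf(path))
    if (is.na(idx)) stop("no channel '", dapiChannel, "' in ", path)
    idx
  }
  refDapi <- streamChannel(roundPaths[[1]], dapiIndexOf(roundPaths[[1]]))

  estimateFor <- function(path) {
    mov <- streamChannel(path, dapiIndexOf(path))
    estimateTransform(refDapi, mov, mode = mode)
  }
  transforms <- list()
  afInfo <- NULL
  if (!is.null(afPath)) {
    tAf <- estimateFor(afPath)
    transforms$af <- tAf
    afInfo <- list(path = afPath, t = tAf, names = chanNamesOf(afPath))
  }
  manifest <- list()
  fileIdx <- 0L
  for (k in seq_along(roundPaths)) {
    path <- roundPaths[[k]]
    nm <- chanNamesOf(path)
    dIdx <- dapiIndexOf(path)
    t <- if (k == 1L) PlanarTransform(mode = mode) else estimateFor(path)
    transforms[[paste0("round", k)]] <- t
    for (j in seq_along(nm)) {
      isDapi <- j == dIdx
      if (isDapi && keepDapi == "first" && k > 1L) next
      ch <- streamChannel(path, j)           # one channel resident
      ch@roundIndex <- as.integer(k)
      if (k > 1L) ch <- applyTransform(ch, t)
      if (!is.null(afInfo) && !isDapi && !(nm[j] %in% skipAfChannels)) {
        afIdx <- match(nm[j], afInfo$names)
        if (is.na(afIdx)) afIdx <- min(j, length(afInfo$names))
        af <- applyTransform(streamChannel(afInfo$path, afIdx), afInfo$t)
        ch <- subtractAutofluorescence(ch, af, scale = afScale)
        rm(af)
      }
      fileIdx <- fileIdx + 1L
      fn <- sprintf("channel_%03d.tif", fileIdx)
      tiff::writeTIFF(ch@pixels / 65535, file.path(outDir, fn),
                      bits.per.sample = 16L, compression = "deflate")
      manifest[[fileIdx]] <- list(file = fn, channel = nm[j], round = k)
      rm(ch)
    }
  }
  jsonlite::write_json(list(
    format = "hyperplexR-aligned-dir",
    pixel_size_um = pixelSize(refDapi),
    channels = manifest,
    transforms = lapply(transforms, function(t) {
      list(mode = t@mode, matrix = t@matrix, residual = t@residual)
    })
  ), file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA,
  matrix = "rowmajor")
  invisible(outDir)
}

#' @rdname alignExperimentDir
#' @export
readAlignedDir <- function(outDir) {
  mf <- jsonlite::read_json(file.path(outDir, "manifest.json"),
                            simplifyVector = FALSE)
  channels <- lapply(mf$channels, function(entry) {
    px <- tiff::readTIFF(file.path(outDir, entry$file), as.is = TRUE)
    ChannelImage(px, mf$pixel_size_um, entry$channel,
                 roundIndex = entry$round)
  })
  HyperplexStack(channels)
}

#' Export estimated transforms as a JSON sidecar
#'
#' Writes the 2x3 matrices and residuals of the transforms attached to an
#' aligned stack (see \code{\link{alignExperiment}}) to a JSON file.
#'
#' @param stack an aligned \linkS4class{HyperplexStack}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeTransforms <- function(stack, path) {
  tl <- attr(stack, "transforms")
  if (is.null(tl)) stop("stack carries no transforms")
  jsonlite::write_json(lapply(tl, function(t) {
    list(mode = t@mode, matrix = t@matrix, residual = t@residual)
  }), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
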