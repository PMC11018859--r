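# Background subtraction and autofluorescence removal.

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence channel by grayscale
#' morphological opening with a flat disc of the given physical diameter
#' (the flat-kernel variant of the classic rolling-ball algorithm) and
#' subtracts it, clamping at zero. Structures smaller than the disc are
#' preserved; flat or slowly varying background is removed.
#'
#' @param img a \linkS4class{ChannelImage}.
#' @param ballDiameterUm structuring-disc diameter in micrometres (default
#'   75, the standard setting for whole-slide immunofluorescence tiles).
#' @return The background-subtracted \linkS4class{ChannelImage}.
#' @export
rollingBallSubtract <- function(img, ballDiameterUm = 75) {
  if (ballDiameterUm <= 0) stop("ballDiameterUm must be > 0")
  diamPx <- umToPx(ballDiameterUm, img@pixelSize)
  if (diamPx < 2) stop("ball diameter smaller than 2 pixels at this pixel size")
  if (diamPx %% 2 == 0) diamPx <- diamPx + 1  # EBImage brushes are odd-sized
  brush <- EBImage::makeBrush(diamPx, shape = "disc")
  bg <- EBImage::opening(EBImage::Image(img@pixels / 65535), brush)
  out <- pmax(img@pixels - as.matrix(EBImage::imageData(bg)) * 65535, 0)
  ChannelImage(out, img@pixelSize, img@channelName, img@roundIndex)
}

#' Pixel-wise autofluorescence subtraction
#'
#' Subtracts an aligned autofluorescence image from a marker channel,
#' element-wise, clamping negative values at zero:
#' \code{out = max(channel - scale * af, 0)}. The autofluorescence channel
#' must already be registered into the same frame and matched to the marker
#' channel by excitation/emission.
#'
#' @param channel marker \linkS4class{ChannelImage}.
#' @param afChannel aligned autofluorescence \linkS4class{ChannelImage}.
#' @param scale multiplier on the autofluorescence image (default 1).
#' @return The corrected \linkS4class{ChannelImage}.
#' @export
subtractAutofluorescence <- function(channel, afChannel, scale = 1.0) {
  if (!all(dim(channel@pixels) == dim(afChannel@pixels))) {
    stop("channel and autofluorescence image differ in shape")
  }
  out <- pmax(channel@pixels - scale * afChannel@pixels, 0)
  ChannelImage(out, channel@pixelSize, channel@channelName, channel@roundIndex)
}
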