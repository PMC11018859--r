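# Intensity-based planar registration: coarse-to-fine pyramid over the
# nuclear (DAPI) channel, minimizing the mean squared intensity difference
# between the reference and the warped moving image. Rigid transforms are
# parametrized as (rotation about the image center, row shift, col shift);
# affine refinement optimizes all six matrix entries.

# Build the 2x3 source-lookup matrix (inverse transform) used by the warp
# kernels from a PlanarTransform.
inverseLookup <- function(t) {
  ti <- invertTransform(t)
  as.numeric(t(ti@matrix))  # (a11, a12, a13, a21, a22, a23)
}

rigidFromParams <- function(p, dims) {
  rigidTransform(thetaDeg = p[1], dr = p[2], dc = p[3], dim = dims)
}

ssdCost <- function(ref, mov, t, stride) {
  r <- cpp_warp_ssd(ref, mov, inverseLookup(t), as.integer(stride))
  if (!is.finite(r$mse) || r$n < 0.05 * length(ref) / stride^2) {
    return(.Machine$double.xmax)
  }
  r$mse
}

#' Estimate the planar transform aligning one DAPI image to another
#'
#' Registers \code{moving} onto \code{reference} by minimizing the mean
#' squared intensity difference over a coarse-to-fine image pyramid
#' (halvings until the shorter edge is about 64 px), with a small integer
#' translation search at the coarsest level followed by Nelder-Mead
#' sub-pixel refinement at every level. Affine mode refines all six matrix
#' entries starting from the rigid solution.
#'
#' @param reference,moving \linkS4class{ChannelImage}s of identical shape
#'   and pixel size (typically the DAPI channels of two rounds).
#' @param mode \code{"rigid"} (default) or \code{"affine"}.
#' @param maxIter iteration cap per pyramid level.
#' @return A \linkS4class{PlanarTransform} mapping moving coordinates into
#'   the reference frame, with the final full-resolution mean squared
#'   difference in \code{@residual}.
#' @export
estimateTransform <- function(reference, moving, mode = c("rigid", "affine"),
                              maxIter = 200L) {
  mode <- match.arg(mode)
  if (!all(dim(reference@pixels) == dim(moving@pixels))) {
    stop("reference and moving images differ in shape")
  }
  if (abs(reference@pixelSize - moving@pixelSize) > 1e-9) {
    stop("reference and moving images differ in pixel size")
  }
  if (stats::sd(reference@pixels) == 0 || stats::sd(moving@pixels) == 0) {
    stop("constant image: no intensity gradient to register on")
  }
  ref <- reference@pixels
  mov <- moving@pixels
  nHalve <- max(0L, ceiling(log2(min(dim(ref)) / 64)))
  pyrRef <- vector("list", nHalve + 1L)
  pyrMov <- vector("list", nHalve + 1L)
  pyrRef[[1L]] <- ref; pyrMov[[1L]] <- mov
  for (k in seq_len(nHalve)) {
    pyrRef[[k + 1L]] <- halveImage(pyrRef[[k]])
    pyrMov[[k + 1L]] <- halveImage(pyrMov[[k]])
  }

  # coarse initialisation: grid search over rotation and integer shift at the
  # second-coarsest level (the coarsest often blurs nuclei below one pixel)
  lvl <- max(1L, nHalve)
  refL <- pyrRef[[lvl]]; movL <- pyrMov[[lvl]]
  dimsL <- dim(refL)
  gstride <- max(1L, floor(min(dimsL) / 64))
  grid <- expand.grid(th = seq(-3, 3, by = 0.5), dr = -6:6, dc = -6:6)
  costs <- mapply(function(th, dr, dc) {
    ssdCost(refL, movL, rigidFromParams(c(th, dr, dc), dimsL), gstride)
  }, grid$th, grid$dr, grid$dc)
  best <- which.min(costs)
  p <- c(grid$th[best], grid$dr[best], grid$dc[best])
  if (lvl < nHalve + 1L) p <- c(p[1], p[2] / 2, p[3] / 2)  # to coarsest scale

  for (lvl in rev(seq_len(nHalve + 1L))) {
    refL <- pyrRef[[lvl]]; movL <- pyrMov[[lvl]]
    dimsL <- dim(refL)
    stride <- max(1L, floor(min(dimsL) / 256))
    iters <- if (lvl == nHalve + 1L) maxIter else ceiling(maxIter / 3)
    fn <- function(q) ssdCost(refL, movL, rigidFromParams(q, dimsL), stride)
    opt <- stats::optim(p, fn, method = "Nelder-Mead",
                        control = list(maxit = iters, reltol = 1e-10,
                                       parscale = c(0.2, 1, 1)))
    p <- opt$par
    if (lvl > 1L) p <- c(p[1], p[2] * 2, p[3] * 2)
  }

  t <- rigidFromParams(p, dim(ref))
  if (mode == "affine") {
    m0 <- as.numeric(t@matrix)
    fnA <- function(q) {
      tq <- PlanarTransform(matrix(q, 2, 3), mode = "affine")
      if (abs(det(tq@matrix[, 1:2])) < 1e-6) return(.Machine$double.xmax)
      ssdCost(ref, mov, tq, max(1L, floor(min(dim(ref)) / 512)))
    }
    optA <- stats::optim(m0, fnA, method = "Nelder-Mead",
                         control = list(maxit = 4L * maxIter, reltol = 1e-12,
                                        parscale = c(1e-3, 1e-3, 1e-3, 1e-3, 1, 1)))
    t <- PlanarTransform(matrix(optA$par, 2, 3), mode = "affine")
  }
  res <- cpp_warp_ssd(ref, mov, inverseLookup(t), 1L)$mse
  initialize(t, residual = res)
}

#' Resample a channel through a planar transform
#'
#' Warps a moving-frame channel into the reference frame by bilinear
#' interpolation; pixels sampling outside the moving image are set to
#' \code{fill}. Integer translations reproduce pixels exactly. Operates on
#' a single channel, honoring the one-channel-resident memory contract.
#'
#' @param channel a \linkS4class{ChannelImage} in the moving frame.
#' @param t \linkS4class{PlanarTransform} mapping moving into reference
#'   coordinates.
#' @param fill value for out-of-frame pixels.
#' @return The resampled \linkS4class{ChannelImage}.
#' @export
applyTransform <- function(channel, t, fill = 0) {
  if (abs(det(t@matrix[, 1:2])) < 1e-12) stop("singular transform")
  out <- cpp_warp_bilinear(channel@pixels, inverseLookup(t), fill)
  ChannelImage(out, channel@pixelSize, channel@channelName, channel@roundIndex)
}
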