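# Region masks: supervised pixel classification baseline, morphological
# clean-up with per-region-class pixel thresholds, and the derived tissue
# niches (expanded lesion context, perivascular band, tumor border).

#' Train-and-apply baseline pixel classifier
#'
#' Small supervised pixel classifier standing in for interactively trained
#' ANN pixel classifiers: per-pixel features are the raw intensities of the
#' selected channels plus Gaussian-smoothed copies at two scales, fed to a
#' single-hidden-layer neural network trained on user scribbles. The result
#' is deterministic given \code{seed}.
#'
#' @param stack a \linkS4class{HyperplexStack}.
#' @param channelSubset channel names to use as features (e.g. vessel
#'   classifiers use CD31, VE-cadherin and CD13).
#' @param scribbles integer matrix in the image frame: 0 = unlabeled,
#'   1 = positive (region), 2 = negative (background).
#' @param label region name for the returned mask.
#' @param smoothSigmas Gaussian smoothing scales (px) for texture features.
#' @param hiddenUnits hidden-layer size of the classifier.
#' @param seed RNG seed for weight initialisation.
#' @return A \linkS4class{RegionMask} with provenance \code{"classifier"}.
#' @export
classifyPixels <- function(stack, channelSubset, scribbles, label = "region",
                           smoothSigmas = c(2, 4), hiddenUnits = 4L,
                           seed = 1L) {
  if (!all(channelSubset %in% stack@markerNames)) {
    stop("channels absent from stack: ",
         paste(setdiff(channelSubset, stack@markerNames), collapse = ", "))
  }
  nPos <- sum(scribbles == 1L)
  nNeg <- sum(scribbles == 2L)
  if (nPos == 0L || nNeg == 0L) {
    stop("scribbles must contain at least one positive and one negative region")
  }
  feats <- list()
  for (nm in channelSubset) {
    px <- imageData(stack, nm) / 65535
    feats[[nm]] <- as.numeric(px)
    for (s in smoothSigmas) {
      sm <- EBImage::gblur(EBImage::Image(px), sigma = s)
      feats[[paste0(nm, "_s", s)]] <- as.numeric(EBImage::imageData(sm))
    }
  }
  X <- do.call(cbind, feats)
  labeled <- which(scribbles != 0L)
  y <- as.numeric(scribbles[labeled] == 1L)
  set.seed(seed)
  fit <- nnet::nnet(X[labeled, , drop = FALSE], y, size = hiddenUnits,
                    decay = 1e-4, maxit = 200, trace = FALSE)
  pred <- stats::predict(fit, X)
  mask <- matrix(pred >= 0.5, nrow(scribbles), ncol(scribbles))
  RegionMask(mask, label = label, provenance = "classifier",
             pixelSize = stack@pixelSize)
}

#' Import an externally produced region mask
#'
#' @param mask logical/numeric matrix (nonzero = foreground).
#' @param label region name.
#' @param pixelSize micrometres per pixel.
#' @return A \linkS4class{RegionMask} with provenance \code{"imported"}.
#' @export
importMask <- function(mask, label, pixelSize = 1) {
  RegionMask(mask != 0, label = label, provenance = "imported",
             pixelSize = pixelSize)
}

#' Morphological clean-up of a region mask
#'
#' Removes connected foreground fragments smaller than
#' \code{minFragmentPx} and fills background holes smaller than
#' \code{minHolePx} (a hole is a background component not touching the
#' image border). Typical settings follow region class: lesion 20000/20000,
#' vessel 20/20, tumor and brain 4000/4000, ECM holes 50 / fragments 300.
#' The operation is idempotent.
#'
#' @param mask a \linkS4class{RegionMask}.
#' @param minHolePx fill background holes with area < this many pixels.
#' @param minFragmentPx remove foreground components with area < this many
#'   pixels.
#' @return The cleaned \linkS4class{RegionMask}.
#' @export
cleanMask <- function(mask, minHolePx = 0, minFragmentPx = 0) {
  if (minHolePx < 0 || minFragmentPx < 0) stop("thresholds must be >= 0")
  m <- mask@mask
  if (minFragmentPx > 0 && any(m)) {
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= minFragmentPx)
    m <- matrix(as.matrix(lab) %in% keep, nrow(m), ncol(m))
  }
  if (minHolePx > 0 && any(!m)) {
    bg <- EBImage::bwlabel(EBImage::Image((!m) * 1))
    bgm <- as.matrix(bg)
    border <- unique(c(bgm[1, ], bgm[nrow(bgm), ], bgm[, 1], bgm[, ncol(bgm)]))
    areas <- tabulate(bgm[bgm > 0])
    fill <- setdiff(which(areas < minHolePx), border)
    m[bgm %in% fill] <- TRUE
  }
  initialize(mask, mask = m, provenance = mask@provenance)
}

#' Expand a region by a physical distance
#'
#' Euclidean dilation: the expanded region contains every pixel within
#' \code{distanceUm} of the input mask (exact distance-transform
#' implementation, so arbitrary radii such as the 750 um lesion context are
#' cheap). With \code{subtractCore = TRUE} the input is removed from the
#' result, yielding an annular band such as the 15 um perivascular niche.
#'
#' @param mask a \linkS4class{RegionMask}.
#' @param distanceUm expansion distance in micrometres (>= 0).
#' @param subtractCore drop the original mask from the result.
#' @param label name for the derived mask (default derived from the input).
#' @return A \linkS4class{RegionMask} with provenance \code{"derived"}.
#' @export
expandRegion <- function(mask, distanceUm, subtractCore = FALSE, label = NULL) {
  if (distanceUm < 0) stop("distanceUm must be >= 0")
  rPx <- distanceUm / mask@pixelSize
  out <- dilateByDistance(mask@mask, rPx)
  if (subtractCore) out <- out & !mask@mask
  RegionMask(out, label = label %||% paste0(mask@label, "_expanded"),
             provenance = "derived", pixelSize = mask@pixelSize)
}

#' Derive the tumor-border niche
#'
#' Finds the tumor-brain interface (pixels of either mask 8-adjacent to the
#' other) and dilates it by \code{widthUm}, giving a band of total width
#' about \code{2 * widthUm} centered on the interface. Non-touching masks
#' yield an empty border with a warning.
#'
#' @param tumor,brain \linkS4class{RegionMask}s in the same frame.
#' @param widthUm half-width of the border band in micrometres (default 70).
#' @return A \linkS4class{RegionMask} labeled \code{"border"}.
#' @export
deriveBorder <- function(tumor, brain, widthUm = 70) {
  if (!all(dim(tumor@mask) == dim(brain@mask))) {
    stop("tumor and brain masks differ in shape")
  }
  interface <- (tumor@mask & dilate8(brain@mask)) |
    (brain@mask & dilate8(tumor@mask))
  if (!any(interface)) {
    warning("tumor and brain masks do not touch; border is empty")
    return(RegionMask(interface, "border", "derived", tumor@pixelSize))
  }
  out <- dilateByDistance(interface, widthUm / tumor@pixelSize)
  RegionMask(out, label = "border", provenance = "derived",
             pixelSize = tumor@pixelSize)
}

#' Assemble the standard derived niches
#'
#' Adds the three compound niches to a region set from its base masks:
#' \code{lesion_context} (lesion expanded 750 um into the parenchyma),
#' \code{perivascular} (vessel expanded 15 um, core removed) and
#' \code{border} (tumor-brain interface dilated 70 um).
#'
#' @param regions a \linkS4class{RegionSet} with base masks
#'   \code{lesion}, \code{vessel}, \code{tumor}, \code{brain} (missing base
#'   masks simply skip their derived niche).
#' @param lesionContextUm,perivascularUm,borderUm the expansion constants.
#' @return The augmented \linkS4class{RegionSet}.
#' @export
deriveNiches <- function(regions, lesionContextUm = 750, perivascularUm = 15,
                         borderUm = 70) {
  nm <- regionNames(regions)
  if ("lesion" %in% nm) {
    regions <- setRegion(regions, expandRegion(getRegion(regions, "lesion"),
                                               lesionContextUm,
                                               label = "lesion_context"))
  }
  if ("vessel" %in% nm) {
    regions <- setRegion(regions, expandRegion(getRegion(regions, "vessel"),
                                               perivascularUm,
                                               subtractCore = TRUE,
                                               label = "perivascular"))
  }
  if (all(c("tumor", "brain") %in% nm)) {
    regions <- setRegion(regions, deriveBorder(getRegion(regions, "tumor"),
                                               getRegion(regions, "brain"),
                                               borderUm))
  }
  regions
}
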