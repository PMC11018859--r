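# Internal helpers shared across modules.

# Convert a physical length in micrometres to pixels (round-half-up).
umToPx <- function(um, pixelSize) floor(um / pixelSize + 0.5)

# Stable sub-seed derivation: keeps derived seeds below 2^31 and decorrelated
# across components under one master seed.
deriveSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

# 2x down-sampling by block mean (odd trailing row/col averaged with itself).
halveImage <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- seq(1, nr, by = 2); ri2 <- pmin(ri + 1, nr)
  ci <- seq(1, nc, by = 2); ci2 <- pmin(ci + 1, nc)
  (x[ri, ci, drop = FALSE] + x[ri2, ci, drop = FALSE] +
     x[ri, ci2, drop = FALSE] + x[ri2, ci2, drop = FALSE]) / 4
}

# Exact Euclidean dilation via distance transform: set of pixels within
# radiusPx (pixel-center metric) of the mask. Fast for arbitrary radii.
dilateByDistance <- function(mask, radiusPx) {
  if (radiusPx <= 0 || !any(mask)) return(mask)
  d <- EBImage::distmap(1 - mask)  # distance of background px to the mask
  mask | (d <= radiusPx)
}

# Binary dilation with a 3x3 box (8-neighborhood), used for adjacency tests.
dilate8 <- function(mask) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  sh <- function(m, dr, dc) {
    res <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    res[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    res
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | sh(mask, dr, dc)
  }
  out
}

# Boundary pixels of a binary mask: foreground pixels 4-adjacent to
# background within the image (the image frame itself is not a border, so
# a region running off the slide has no spurious edge there).
maskBoundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(TRUE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  core & !inner
}

# Per-object centroids of a label map, 0-based pixel coordinates (row, col).
labelCentroids <- function(labels) {
  ids <- seq_len(max(0L, max(labels)))
  if (!length(ids)) return(matrix(numeric(0), 0, 2))
  idx <- which(labels > 0)
  lab <- labels[idx]
  r <- (idx - 1) %% nrow(labels)
  c <- (idx - 1) %/% nrow(labels)
  cbind(row = as.numeric(rowsum(r, lab) / tabulate(lab, length(ids))),
        col = as.numeric(rowsum(c, lab) / tabulate(lab, length(ids))))
}

# Chain-code perimeter of one object's mask using Vossepoel-Smeulders
# corner-corrected weights (accurate to ~1% for smooth digital shapes).
maskPerimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) return(0)
  per <- 0
  for (ct in oc) {
    n <- nrow(ct)
    if (n < 2) { per <- per + 4; next }
    d <- ct - ct[c(2:n, 1), , drop = FALSE]
    diag_step <- d[, 1] != 0 & d[, 2] != 0
    ne <- sum(!diag_step); no <- sum(diag_step)
    # corner count: direction changes along the chain
    dirs <- atan2(d[, 2], d[, 1])
    ncorner <- sum(dirs != c(dirs[-1], dirs[1]))
    per <- per + 0.980 * ne + 1.406 * no - 0.091 * ncorner
  }
  per
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
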