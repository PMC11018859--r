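# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately naive (loops, exhaustive scans) and never share code with the
# implementation paths they check.

# Binary disk mask centered in an n x n frame.
diskMask <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - center[1])^2 + (j - center[2])^2) <= radius^2
}

# Sparse Gaussian-blob scene resembling a DAPI channel.
blobScene <- function(n, nBlobs, seed, amp = 4000, sigma = 3) {
  set.seed(seed)
  img <- matrix(0, n, n)
  cx <- runif(nBlobs, 20, n - 20)
  cy <- runif(nBlobs, 20, n - 20)
  for (i in seq_len(nBlobs)) {
    rs <- max(1, floor(cx[i] - 4 * sigma)):min(n, ceiling(cx[i] + 4 * sigma))
    cs <- max(1, floor(cy[i] - 4 * sigma)):min(n, ceiling(cy[i] + 4 * sigma))
    img[rs, cs] <- img[rs, cs] +
      amp * exp(-outer((rs - cx[i])^2, (cs - cy[i])^2, "+") / (2 * sigma^2))
  }
  list(img = pmin(img + 100, 65535), centers = cbind(cx, cy) - 1)
}

# Brute-force grayscale opening (min filter then max filter) with an
# explicit disk offset set: the morphological oracle for rolling-ball.
bruteOpening <- function(img, radiusPx) {
  off <- which(outer(-radiusPx:radiusPx, -radiusPx:radiusPx,
                     function(a, b) a^2 + b^2) <= radiusPx^2, arr.ind = TRUE)
  off <- off - radiusPx - 1
  nr <- nrow(img); nc <- ncol(img)
  slide <- function(x, fun, pad) {
    out <- matrix(pad, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      rr <- r + off[, 1]; cc <- c + off[, 2]
      # replicate border (clamp), matching standard morphology padding
      rr <- pmin(pmax(rr, 1), nr); cc <- pmin(pmax(cc, 1), nc)
      out[r, c] <- fun(x[cbind(rr, cc)])
    }
    out
  }
  slide(slide(img, min, Inf), max, -Inf)
}

# Exhaustive per-pixel overlap-resolution oracle: for each pixel, compute
# each mask's interior distance by scanning that mask's background pixels.
bruteResolve <- function(masks) {
  dims <- dim(masks[[1]])
  dmaps <- lapply(masks, function(m) {
    bg <- which(!m, arr.ind = TRUE)
    d <- matrix(0, dims[1], dims[2])
    for (r in seq_len(dims[1])) for (c in seq_len(dims[2])) {
      if (m[r, c]) {
        d[r, c] <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
      }
    }
    d
  })
  out <- matrix(0L, dims[1], dims[2])
  for (r in seq_len(dims[1])) for (c in seq_len(dims[2])) {
    v <- vapply(dmaps, function(d) d[r, c], 0)
    top <- max(v)
    if (top > 0 && sum(v == top) == 1L) out[r, c] <- which.max(v)
  }
  out
}

# O(n^2) loop oracles for nearest-neighbor distances and radius queries.
bruteNNDist <- function(ax, ay, bx, by) {
  vapply(seq_along(ax), function(i) {
    sqrt(min((bx - ax[i])^2 + (by - ay[i])^2))
  }, 0)
}

bruteRadiusCounts <- function(x, y, types, radius) {
  lev <- sort(unique(types))
  n <- length(x)
  out <- matrix(0L, n, length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= radius^2 + 1e-9) {
      out[i, types[j]] <- out[i, types[j]] + 1L
    }
  }
  out
}

# Adjusted Rand index between two labelings (closed form, independent of
# any clustering package).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  exp_ <- ai * bj / nn
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}

# Purity of clusters against ground-truth labels.
clusterPurity <- function(cluster, truth) {
  tab <- table(cluster, truth)
  sum(apply(tab, 1, max)) / sum(tab)
}
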