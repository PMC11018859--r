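# Cellular neighborhoods: per-cell composition of cell types within a
# physical radius, and k-means clustering of pooled composition profiles
# into recurrent neighborhoods (CNs).

#' Per-cell neighborhood composition profiles
#'
#' For every cell, the cells with centroid distance <= \code{radiusUm}
#' (self excluded) form its neighborhood; the profile is the fraction of
#' each cell type among those neighbors. Cells with no neighbor are
#' flagged isolated and carry zero fractions.
#'
#' @param table cell table with coordinates in micrometres.
#' @param radiusUm neighborhood radius (default 30).
#' @return Data.frame: image_id, group, cell_id (row within table),
#'   cell_type, n_neighbors, isolated, and one \code{frac__<type>} column
#'   per cell type (fractions summing to 1 for non-isolated cells).
#' @export
neighborhoods <- function(table, radiusUm = 30) {
  table <- checkCellTable(table)
  types <- sort(unique(table$cell_type))
  out <- vector("list", length(unique(table$image_id)))
  i <- 0L
  for (img in split(table, table$image_id)) {
    xy <- cbind(img$x_um, img$y_um)
    n <- nrow(xy)
    d2 <- outer(rowSums(xy^2), rowSums(xy^2), "+") - 2 * xy %*% t(xy)
    adj <- d2 <= radiusUm^2 + 1e-9
    diag(adj) <- FALSE
    Y <- outer(img$cell_type, types, "==") * 1
    counts <- adj %*% Y
    nn <- rowSums(counts)
    frac <- counts / ifelse(nn > 0, nn, 1)
    colnames(frac) <- paste0("frac__", types)
    res <- data.frame(image_id = img$image_id, group = img$group,
                      cell_id = seq_len(n), cell_type = img$cell_type,
                      n_neighbors = as.integer(nn), isolated = nn == 0)
    i <- i + 1L
    out[[i]] <- cbind(res, as.data.frame(frac))
  }
  do.call(rbind, out)
}

#' Cluster pooled neighborhood profiles into cellular neighborhoods
#'
#' K-means on the composition fractions of all non-isolated cells pooled
#' across images, with a fixed seed. Isolated cells receive CN \code{NA}.
#'
#' @param profiles output of \code{\link{neighborhoods}} (pooled across all
#'   images of a dataset).
#' @param k number of cellular neighborhoods (default 15).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return List: \code{cn} (CN id per profile row), \code{centers}
#'   (per-CN mean composition, the heatmap input), \code{perImage}
#'   (percent of each CN per image), \code{profiles} (input with a
#'   \code{cn} column).
#' @export
clusterNeighborhoods <- function(profiles, k = 15L, seed = 1L, nstart = 10L) {
  if (k < 1L) stop("k must be >= 1")
  fracCols <- grep("^frac__", colnames(profiles), value = TRUE)
  use <- !profiles$isolated
  X <- as.matrix(profiles[use, fracCols, drop = FALSE])
  if (nrow(X) < k) stop("fewer non-isolated profiles than clusters")
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L)
  cn <- rep(NA_integer_, nrow(profiles))
  cn[use] <- km$cluster
  profiles$cn <- cn
  centers <- as.data.frame(km$centers)
  centers$cn <- seq_len(k)
  perImage <- do.call(rbind, lapply(split(profiles[use, ],
                                          profiles$image_id[use]),
    function(s) data.frame(image_id = s$image_id[1], group = s$group[1],
                           cn = seq_len(k),
                           percent = 100 * tabulate(s$cn, k) / nrow(s))))
  rownames(perImage) <- NULL
  list(cn = cn, centers = centers, perImage = perImage, profiles = profiles)
}
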