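# Semi-supervised phenotyping: percentile-clipped min-max scaling of marker
# MFIs, a batch-trained self-organizing map (rectangular grid, Gaussian
# neighborhood with decaying radius), hierarchical metaclustering of the
# node codebook, and annotation mapping back onto cells.

#' Scale marker intensities for clustering
#'
#' Per marker: values are clipped at the \code{clipQuantile} quantile
#' (linear-interpolation quantile definition, type 7) and min-max scaled to
#' [0, 1], so the clip value maps to 1 and larger outliers no longer
#' dominate the scale. Constant markers become all-zero with a warning.
#'
#' @param table cell table carrying MFI columns
#'   (\code{mfi__<marker>__<zone>}).
#' @param config named character vector: for each classification marker the
#'   zone whose MFI feeds clustering, \code{"nucleus"} or \code{"cell"}
#'   (per the marker's biology).
#' @param clipQuantile upper clipping quantile (default 0.997).
#' @return List with \code{features} (cells x markers matrix in [0, 1]) and
#'   \code{scaling} (per-marker min and clip value, reusable on new data
#'   via \code{applyScaling}).
#' @export
scaleMarkers <- function(table, config, clipQuantile = 0.997) {
  if (nrow(table) < 2L) stop("at least 2 cells required")
  cols <- paste0("mfi__", names(config), "__", unname(config))
  missing <- setdiff(cols, colnames(table))
  if (length(missing)) stop("columns absent: ", paste(missing, collapse = ", "))
  X <- as.matrix(table[, cols, drop = FALSE])
  colnames(X) <- names(config)
  lo <- apply(X, 2, min, na.rm = TRUE)
  hi <- apply(X, 2, stats::quantile, probs = clipQuantile, na.rm = TRUE,
              type = 7)
  scaling <- data.frame(marker = names(config), min = lo, clip = hi)
  list(features = applyScaling(X, scaling), scaling = scaling)
}

#' @rdname scaleMarkers
#' @param X raw feature matrix with markers as columns.
#' @param scaling the scaling table returned by \code{scaleMarkers}.
#' @export
applyScaling <- function(X, scaling) {
  out <- X
  for (j in seq_len(ncol(X))) {
    lo <- scaling$min[j]; hi <- scaling$clip[j]
    if (hi <= lo) {
      warning("marker '", colnames(X)[j], "' is constant; scaled to 0")
      out[, j] <- 0
    } else {
      out[, j] <- (pmin(X[, j], hi) - lo) / (hi - lo)
    }
  }
  out[out < 0] <- 0
  out
}

somGridDistance2 <- function(grid) {
  pos <- expand.grid(r = seq_len(grid[1]), c = seq_len(grid[2]))
  as.matrix(stats::dist(pos))^2
}

#' Train a self-organizing map on scaled features
#'
#' Batch SOM on a rectangular node grid (default 10 x 10 = 100 nodes):
#' every sweep maps all cells to their best-matching unit and replaces each
#' codebook vector by the Gaussian-neighborhood-weighted mean of the data,
#' with the neighborhood radius decaying geometrically from
#' \code{sigma[1]} to \code{sigma[2]} over the sweeps. Deterministic given
#' \code{seed} (codebook initialised from sampled data rows).
#'
#' @param features cells x markers matrix scaled to [0, 1].
#' @param grid node grid (rows, cols), default \code{c(10, 10)}.
#' @param seed RNG seed.
#' @param epochs number of batch sweeps (default 30).
#' @param sigma neighborhood radius schedule (start, end).
#' @return A \linkS4class{SOMModel} with the final mean quantization error.
#' @export
trainSOM <- function(features, grid = c(10L, 10L), seed = 1L, epochs = 30L,
                     sigma = c(5, 0.5)) {
  features <- as.matrix(features)
  nNodes <- prod(grid)
  if (nrow(features) < nNodes) {
    stop("need at least as many cells as nodes (", nNodes, ")")
  }
  set.seed(seed)
  codebook <- features[sample.int(nrow(features), nNodes), , drop = FALSE]
  gd2 <- somGridDistance2(grid)
  sig <- sigma[1] * (sigma[2] / sigma[1])^(seq(0, 1, length.out = epochs))
  x2 <- rowSums(features^2)
  for (e in seq_len(epochs)) {
    d2 <- outer(x2, rowSums(codebook^2), "+") - 2 * features %*% t(codebook)
    bmu <- max.col(-d2, ties.method = "first")
    H <- exp(-gd2 / (2 * sig[e]^2))
    cnt <- tabulate(bmu, nNodes)
    xsum <- matrix(0, nNodes, ncol(features))
    hit <- sort(unique(bmu))
    xsum[hit, ] <- rowsum(features, bmu)
    num <- H %*% xsum
    den <- as.numeric(H %*% cnt)
    upd <- den > 1e-300
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  d2 <- outer(x2, rowSums(codebook^2), "+") - 2 * features %*% t(codebook)
  qe <- mean(sqrt(pmax(apply(d2, 1, min), 0)))
  new("SOMModel", grid = as.integer(grid), codebook = codebook,
      seed = as.integer(seed), epochs = as.integer(epochs),
      sigma = as.numeric(sigma), quantError = qe)
}

#' Assign cells to SOM nodes
#'
#' Maps each cell to its nearest codebook vector (Euclidean); ties break to
#' the lowest node id.
#'
#' @param model a \linkS4class{SOMModel}.
#' @param features cells x markers matrix in the model's feature space.
#' @return Integer vector of node ids (1-based).
#' @export
assignNodes <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(model@codebook)) {
    stop("feature dimension does not match the codebook")
  }
  d2 <- outer(rowSums(features^2), rowSums(model@codebook^2), "+") -
    2 * features %*% t(model@codebook)
  max.col(-round(d2, 12), ties.method = "first")
}

#' Metacluster SOM nodes by hierarchical clustering
#'
#' Agglomerative clustering of the codebook vectors (Euclidean distance,
#' average linkage by default) cut at \code{k} metaclusters. Deterministic.
#'
#' @param model a \linkS4class{SOMModel}.
#' @param k number of metaclusters (1..number of nodes).
#' @param linkage linkage method passed to \code{hclust}.
#' @return Integer vector: metacluster id per node.
#' @export
metaclusterNodes <- function(model, k, linkage = "average") {
  nNodes <- nrow(model@codebook)
  if (k < 1L || k > nNodes) stop("k must be in 1..", nNodes)
  hc <- stats::hclust(stats::dist(model@codebook), method = linkage)
  as.integer(stats::cutree(hc, k = k))
}

#' Annotate cells from a node annotation map
#'
#' Populates the \code{cell_type} column of a cell table from its node
#' assignments and a total node-to-label mapping; errors on any node
#' present in the data but absent from the annotation.
#'
#' @param table cell table.
#' @param nodeIds per-cell node ids (from \code{\link{assignNodes}}, or
#'   metacluster ids).
#' @param annotation named character vector or list mapping node id (as
#'   character) to a cell-type label.
#' @return The table with a \code{cell_type} column.
#' @export
annotateCells <- function(table, nodeIds, annotation) {
  ids <- sort(unique(nodeIds))
  missing <- setdiff(as.character(ids), names(annotation))
  if (length(missing)) {
    stop("annotation missing for node(s): ", paste(missing, collapse = ", "))
  }
  lab <- unlist(annotation)[as.character(nodeIds)]
  if (any(!nzchar(lab))) stop("empty cell-type label in annotation")
  table$cell_type <- unname(lab)
  table
}

#' Persist / restore a SOM model as portable JSON
#'
#' @param model a \linkS4class{SOMModel}.
#' @param scaling optional scaling table from \code{\link{scaleMarkers}}.
#' @param path JSON file.
#' @return \code{path} invisibly / the restored list with elements
#'   \code{model} and \code{scaling}.
#' @export
writeSOMModel <- function(model, path, scaling = NULL) {
  jsonlite::write_json(list(
    grid = model@grid, codebook = model@codebook, seed = model@seed,
    epochs = model@epochs, sigma = model@sigma, quantError = model@quantError,
    markers = colnames(model@codebook), scaling = scaling
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeSOMModel
#' @export
readSOMModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cb <- j$codebook
  if (!is.matrix(cb)) cb <- matrix(unlist(cb), nrow = prod(j$grid), byrow = TRUE)
  colnames(cb) <- j$markers
  model <- new("SOMModel", grid = as.integer(j$grid), codebook = cb,
               seed = as.integer(j$seed), epochs = as.integer(j$epochs),
               sigma = as.numeric(j$sigma), quantError = j$quantError)
  list(model = model, scaling = j$scaling)
}

#' Read marker configuration or node annotation from YAML
#'
#' Marker configuration YAML maps marker names to the zone feeding
#' clustering (\code{nucleus} or \code{cell}); annotation YAML maps node or
#' metacluster ids to cell-type labels.
#'
#' @param path YAML file.
#' @return Named character vector.
#' @export
readMarkerConfig <- function(path) {
  cfg <- unlist(yaml::read_yaml(path))
  bad <- !cfg %in% c("nucleus", "cell")
  if (any(bad)) stop("invalid zone for marker(s): ",
                     paste(names(cfg)[bad], collapse = ", "))
  cfg
}

#' @rdname readMarkerConfig
#' @export
readNodeAnnotation <- function(path) {
  ann <- unlist(yaml::read_yaml(path))
  storage.mode(ann) <- "character"
  ann
}
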