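# Cell expansion and per-cell measurement. Nuclei are dilated by a physical
# radius into pairwise-disjoint cells (nearest-nucleus assignment, capped at
# a multiple of the nucleus area), and four zones are measured per object:
# nucleus, cytoplasm, whole cell, and a boundary membrane ring.

#' Expand nuclei into constrained cell masks
#'
#' Dilates every nucleus by up to \code{radiusUm}, assigning each expansion
#' pixel to its nearest nucleus (Euclidean, so frontiers between adjacent
#' cells meet at the equidistant line and cells stay pairwise disjoint).
#' Expansion is additionally capped per object so that
#' \code{area(cell) <= maxAreaRatio * area(nucleus)}, dropping the farthest
#' candidate pixels first. The physical radius is converted to pixels with
#' round-half-up.
#'
#' @param lm nuclear \linkS4class{LabelMap}.
#' @param radiusUm expansion radius in micrometres (default 2.5).
#' @param maxAreaRatio cell/nucleus area cap (default 1.5).
#' @param membraneWidth membrane ring width in pixels (default 1).
#' @return A \linkS4class{CellZones}.
#' @export
expandCells <- function(lm, radiusUm = 2.5, maxAreaRatio = 1.5,
                        membraneWidth = 1L) {
  labels <- lm@labels
  nObj <- length(lm@probabilities)
  radiusPx <- umToPx(radiusUm, lm@pixelSize)
  cell <- labels
  if (radiusPx > 0 && nObj > 0) {
    nl <- cpp_nearest_label(labels, as.numeric(radiusPx))
    cand <- which(labels == 0L & nl$label > 0L)
    if (length(cand)) {
      candLab <- nl$label[cand]
      candD2 <- nl$dist2[cand]
      areaN <- tabulate(labels[labels > 0L], nObj)
      budget <- pmax(floor(maxAreaRatio * areaN) - areaN, 0)
      ord <- order(candLab, candD2, cand)
      lab_s <- candLab[ord]
      rk <- stats::ave(seq_along(lab_s), lab_s, FUN = seq_along)
      keep <- rk <= budget[lab_s]
      cell[cand[ord][keep]] <- lab_s[keep]
    }
  }
  new("CellZones", nucleusLabels = labels, cellLabels = cell,
      membraneWidth = as.integer(membraneWidth),
      probabilities = lm@probabilities, pixelSize = lm@pixelSize)
}

# Label matrix of the membrane ring: cell pixels within `width` steps of a
# pixel belonging to a different cell or to background (4-adjacency).
membraneLabels <- function(zones) {
  lab <- zones@cellLabels
  nr <- nrow(lab); nc <- ncol(lab)
  interior <- lab
  for (w in seq_len(zones@membraneWidth)) {
    pad <- matrix(0L, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- interior
    same <- (pad[1:nr, 2:(nc + 1)] == interior) &
      (pad[3:(nr + 2), 2:(nc + 1)] == interior) &
      (pad[2:(nr + 1), 1:nc] == interior) &
      (pad[2:(nr + 1), 3:(nc + 2)] == interior)
    interior[!same] <- 0L
  }
  out <- lab
  out[interior > 0L] <- 0L
  out
}

zoneLabelMatrices <- function(zones) {
  cyto <- zones@cellLabels
  cyto[zones@nucleusLabels > 0L] <- 0L
  list(nucleus = zones@nucleusLabels,
       cytoplasm = cyto,
       cell = zones@cellLabels,
       membrane = membraneLabels(zones))
}

# Per-object mean of img over a zone label matrix; NA for empty zones.
zoneMeans <- function(img, zlab, nObj) {
  idx <- zlab > 0L
  if (!any(idx)) return(rep(NA_real_, nObj))
  sums <- rowsum(img[idx], zlab[idx])
  counts <- tabulate(zlab[idx], nObj)
  out <- rep(NA_real_, nObj)
  out[as.integer(rownames(sums))] <- sums[, 1]
  out / ifelse(counts > 0, counts, NA)
}

# Per-object perimeter via chain-code tracing on the object's cropped mask.
objectPerimeters <- function(labels, nObj) {
  per <- numeric(nObj)
  if (nObj == 0L) return(per)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  r <- (idx - 1L) %% nrow(labels) + 1L
  c <- (idx - 1L) %/% nrow(labels) + 1L
  sp <- split(seq_along(lab), lab)
  for (nm in names(sp)) {
    k <- as.integer(nm)
    rows <- r[sp[[nm]]]; cols <- c[sp[[nm]]]
    sub <- matrix(FALSE, max(rows) - min(rows) + 3, max(cols) - min(cols) + 3)
    sub[cbind(rows - min(rows) + 2L, cols - min(cols) + 2L)] <- TRUE
    per[k] <- maskPerimeter(sub)
  }
  per
}

#' Measure single cells over an aligned stack
#'
#' Produces one record per cell: centroid (micrometres), morphometrics of
#' nucleus and cell (area, perimeter, circularity = 4 pi A / P^2), mean
#' fluorescence intensity of every marker in every zone
#' (\code{mfi__<marker>__<zone>}), distance from the nucleus centroid to
#' the nearest boundary pixel of each region mask (\code{dist__<region>},
#' micrometres) and region membership flags (\code{in__<region>}). Cells
#' whose centroid falls in the \code{excluded} region are dropped; empty
#' zones yield NA, not zero.
#'
#' @param stack a \linkS4class{HyperplexStack} sharing the zones' frame.
#' @param zones a \linkS4class{CellZones}.
#' @param regions optional \linkS4class{RegionSet}.
#' @param markers marker names to measure (default all).
#' @return A \code{data.frame}, one row per cell.
#' @export
measureCells <- function(stack, zones, regions = NULL, markers = NULL) {
  if (!all(dim(stack@channels[[1L]]@pixels) == dim(zones@cellLabels))) {
    stop("stack and zones differ in shape")
  }
  markers <- markers %||% stack@markerNames
  nObj <- length(zones@probabilities)
  ps <- zones@pixelSize
  zl <- zoneLabelMatrices(zones)

  cent <- labelCentroids(zones@nucleusLabels)  # 0-based (row, col)
  df <- data.frame(cell_id = seq_len(nObj),
                   x_um = cent[, "col"] * ps,
                   y_um = cent[, "row"] * ps,
                   probability = zones@probabilities)

  areaN <- tabulate(zl$nucleus[zl$nucleus > 0L], nObj)
  areaC <- tabulate(zl$cell[zl$cell > 0L], nObj)
  perN <- objectPerimeters(zl$nucleus, nObj)
  perC <- objectPerimeters(zl$cell, nObj)
  df$nucleus_area <- areaN * ps^2
  df$nucleus_perimeter <- perN * ps
  # corrected chain-code perimeters can dip below the isoperimetric bound on
  # near-circular digital shapes; cap at 1 as digital-morphometry tools do
  df$nucleus_circularity <- pmin(4 * pi * areaN / perN^2, 1)
  df$cell_area <- areaC * ps^2
  df$cell_perimeter <- perC * ps
  df$cell_circularity <- pmin(4 * pi * areaC / perC^2, 1)

  for (nm in markers) {
    img <- imageData(stack, nm)
    for (z in names(zl)) {
      df[[paste0("mfi__", nm, "__", z)]] <- zoneMeans(img, zl[[z]], nObj)
    }
  }

  keep <- rep(TRUE, nObj)
  if (!is.null(regions)) {
    ci <- cbind(pmin(pmax(round(cent[, "row"]) + 1, 1), nrow(zones@cellLabels)),
                pmin(pmax(round(cent[, "col"]) + 1, 1), ncol(zones@cellLabels)))
    for (lab in regionNames(regions)) {
      mask <- getRegion(regions, lab)@mask
      inR <- mask[ci]
      if (lab == "excluded") {
        keep <- keep & !inR
      }
      border <- maskBoundary(mask)
      if (any(border)) {
        dmap <- as.matrix(EBImage::distmap(EBImage::Image((!border) * 1)))
        df[[paste0("dist__", lab)]] <- dmap[ci] * ps
      } else {
        df[[paste0("dist__", lab)]] <- NA_real_
      }
      df[[paste0("in__", lab)]] <- inR
    }
  }
  df[keep, , drop = FALSE]
}

#' Export a cell table
#'
#' Writes the per-cell measurement table as CSV, or Parquet when the arrow
#' package is available.
#'
#' @param table data.frame from \code{\link{measureCells}} (or enriched by
#'   later stages).
#' @param path output file; format chosen by extension (.csv or .parquet).
#' @return \code{path}, invisibly.
#' @export
writeCellTable <- function(table, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("Parquet export requires the arrow package")
    }
    arrow::write_parquet(table, path)
  } else {
    utils::write.csv(table, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("Parquet import requires the arrow package")
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path)
  }
}
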