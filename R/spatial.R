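# Composition tables, nearest-neighbor distance summaries and Shannon
# diversity. Cell tables are plain data.frames with columns image_id,
# group, x_um, y_um, cell_type, and optional in__<region> membership flags.

checkCellTable <- function(table, need = c("image_id", "x_um", "y_um",
                                           "cell_type")) {
  miss <- setdiff(need, colnames(table))
  if (length(miss)) stop("cell table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!nrow(table)) stop("empty cell table")
  if (!"group" %in% colnames(table)) table$group <- "all"
  table
}

#' Cellular composition per image and region
#'
#' Counts and percent-of-total of every cell type, per image, overall and
#' within each region membership column (\code{in__<region>}). Percents
#' within one (image, region) sum to 100.
#'
#' @param table cell table with \code{cell_type} populated.
#' @param regions optional character vector of region names to tabulate
#'   (default: every \code{in__} column present).
#' @return A data.frame with columns image_id, group, region, cell_type,
#'   n, percent.
#' @export
composition <- function(table, regions = NULL) {
  table <- checkCellTable(table)
  regCols <- paste0("in__", regions %||%
                      sub("^in__", "", grep("^in__", colnames(table),
                                            value = TRUE)))
  types <- sort(unique(table$cell_type))
  out <- list()
  tally <- function(sub, regionName) {
    if (!nrow(sub)) return(NULL)
    n <- table(factor(sub$cell_type, levels = types))
    data.frame(image_id = sub$image_id[1], group = sub$group[1],
               region = regionName, cell_type = types,
               n = as.integer(n), percent = 100 * as.numeric(n) / sum(n))
  }
  for (img in split(table, table$image_id)) {
    out[[length(out) + 1L]] <- tally(img, "all")
    for (rc in regCols) {
      if (!rc %in% colnames(img)) next
      out[[length(out) + 1L]] <- tally(img[img[[rc]] %in% TRUE, , drop = FALSE],
                                       sub("^in__", "", rc))
    }
  }
  do.call(rbind, out)
}

# Min distance from each row of a to its nearest row of b (micrometres).
nearestCrossDistance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Nearest-neighbor distances between cell types
#'
#' For every image and ordered pair of distinct cell types (A, B): the mean
#' over A-cells of the Euclidean distance to the nearest B-cell. Per-image
#' means are then summarised per group as mean and standard deviation
#' across images. Pairs with either type absent from an image are missing,
#' not zero.
#'
#' @param table cell table.
#' @return List of class \code{DistanceSummary}: \code{perImage}
#'   (image_id, group, type_a, type_b, mean_dist) and \code{summary}
#'   (group, type_a, type_b, mean, sd, n_images).
#' @export
nnDistances <- function(table) {
  table <- checkCellTable(table)
  per <- list()
  for (img in split(table, table$image_id)) {
    coords <- split(data.frame(img$x_um, img$y_um), img$cell_type)
    types <- names(coords)
    for (a in types) for (b in types) {
      if (a == b) next
      per[[length(per) + 1L]] <- data.frame(
        image_id = img$image_id[1], group = img$group[1],
        type_a = a, type_b = b,
        mean_dist = mean(nearestCrossDistance(as.matrix(coords[[a]]),
                                              as.matrix(coords[[b]]))))
    }
  }
  perImage <- do.call(rbind, per)
  agg <- do.call(rbind, lapply(
    split(perImage, perImage[, c("group", "type_a", "type_b")], drop = TRUE),
    function(s) data.frame(group = s$group[1], type_a = s$type_a[1],
                           type_b = s$type_b[1], mean = mean(s$mean_dist),
                           sd = stats::sd(s$mean_dist), n_images = nrow(s))))
  rownames(agg) <- NULL
  structure(list(perImage = perImage, summary = agg),
            class = "DistanceSummary")
}

#' Shannon diversity of cell-type composition
#'
#' Shannon index H' = -sum(p_i log p_i) (natural log, positive proportions
#' only) per image, and its mean per group (the mu-H' reported alongside
#' proximity networks). Invariant under type relabeling and bounded by
#' log(number of types).
#'
#' @param table cell table (or a composition table from
#'   \code{\link{composition}} restricted to one region).
#' @param logBase base of the logarithm (default natural).
#' @return List: \code{perImage} (image_id, group, H) and \code{perGroup}
#'   (group, meanH).
#' @export
shannonIndex <- function(table, logBase = exp(1)) {
  if (all(c("percent", "region") %in% colnames(table))) {
    table <- table[table$region == "all" & table$n > 0, , drop = FALSE]
    props <- split(table$percent / 100, table$image_id)
    groups <- vapply(split(as.character(table$group), table$image_id),
                     function(g) g[1], "")
  } else {
    table <- checkCellTable(table)
    props <- lapply(split(table$cell_type, table$image_id),
                    function(ct) as.numeric(table(ct)) / length(ct))
    groups <- vapply(split(as.character(table$group), table$image_id),
                     function(g) g[1], "")
  }
  H <- vapply(props, function(p) {
    p <- p[p > 0]
    -sum(p * log(p, base = logBase))
  }, 0)
  perImage <- data.frame(image_id = names(props), group = unname(groups),
                         H = unname(H))
  perGroup <- do.call(rbind, lapply(split(perImage, perImage$group),
                                    function(s) data.frame(group = s$group[1],
                                                           meanH = mean(s$H))))
  rownames(perGroup) <- NULL
  list(perImage = perImage, perGroup = perGroup)
}
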