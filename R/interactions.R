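# Classical permutation test of cell-cell interaction: the observed
# statistic for an ordered type pair (A, B) is the mean number of
# B-neighbors per A-cell on the fixed spatial graph; the null distribution
# comes from permuting cell-type labels within the image (type counts
# preserved), and two one-tailed add-one p values classify each pair as
# attracting (+1), avoiding (-1) or neutral (0).

interactionStats <- function(adjY, Y, counts) {
  # adjY = adj %*% Y (neighbor counts of each type per cell)
  S <- crossprod(Y, adjY)          # total B-neighbor count over A-cells
  S / counts                        # mean per A-cell (rows = A, cols = B)
}

testInteractionsImage <- function(img, radiusUm, nPerm, alpha, seed) {
  types <- sort(unique(img$cell_type))
  nT <- length(types)
  xy <- cbind(img$x_um, img$y_um)
  n <- nrow(xy)
  d2 <- outer(rowSums(xy^2), rowSums(xy^2), "+") - 2 * xy %*% t(xy)
  adj <- (d2 <= radiusUm^2 + 1e-9) * 1
  diag(adj) <- 0
  Y <- outer(img$cell_type, types, "==") * 1
  counts <- matrix(colSums(Y), nT, nT)
  obs <- interactionStats(adj %*% Y, Y, counts)
  ge <- matrix(0L, nT, nT)
  le <- matrix(0L, nT, nT)
  set.seed(seed)
  for (p in seq_len(nPerm)) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    Sp <- interactionStats(adj %*% Yp, Yp, counts)
    ge <- ge + (Sp >= obs - 1e-9)
    le <- le + (Sp <= obs + 1e-9)
  }
  pGt <- (1 + ge) / (nPerm + 1)
  pLt <- (1 + le) / (nPerm + 1)
  sig <- (pGt <= alpha) - (pLt <= alpha)
  data.frame(image_id = img$image_id[1], group = img$group[1],
             type_a = rep(types, times = nT), type_b = rep(types, each = nT),
             obs = as.numeric(obs), p_gt = as.numeric(pGt),
             p_lt = as.numeric(pLt), p_sum = as.numeric(pGt + pLt),
             sigval = as.integer(sig))
}

#' Permutation test of cell-cell interactions
#'
#' Classical label-permutation interaction test, per image: for every
#' ordered pair of cell types present, the mean count of B-type neighbors
#' per A-type cell within \code{radiusUm} is compared against \code{nPerm}
#' random reassignments of the cell-type labels (counts preserved,
#' geometry fixed). Add-one one-tailed p values give
#' \code{p_gt} (attraction) and \code{p_lt} (avoidance), a significance
#' indicator \code{sigval} (+1 attraction, -1 avoidance at level
#' \code{alpha}), and their per-group sums across images
#' (\code{sum_sigval}). Deterministic: each image's permutations are
#' seeded from the master seed and the image id.
#'
#' @param table cell table.
#' @param radiusUm interaction radius in micrometres (default 30; pass 15
#'   to treat the 30 um figure as a diameter).
#' @param nPerm number of permutations (default 1000).
#' @param alpha significance level (default 0.01).
#' @param seed master seed.
#' @return List of class \code{InteractionResult}: \code{perImage} and
#'   \code{perGroup} (group, type_a, type_b, sum_sigval, n_images,
#'   mean_p_sum).
#' @export
testInteractions <- function(table, radiusUm = 30, nPerm = 1000L,
                             alpha = 0.01, seed = 1L) {
  table <- checkCellTable(table)
  per <- lapply(split(table, table$image_id), function(img) {
    if (length(unique(img$cell_type)) < 2L) return(NULL)
    testInteractionsImage(img, radiusUm, nPerm, alpha,
                          deriveSeed(seed, "interactions", img$image_id[1]))
  })
  perImage <- do.call(rbind, per)
  if (is.null(perImage)) {
    warning("no image carried two or more cell types; empty result")
    empty <- data.frame(image_id = character(), group = character(),
                        type_a = character(), type_b = character(),
                        obs = numeric(), p_gt = numeric(), p_lt = numeric(),
                        p_sum = numeric(), sigval = integer())
    return(structure(list(perImage = empty,
                          perGroup = empty[, c("group", "type_a", "type_b")]),
                     class = "InteractionResult"))
  }
  rownames(perImage) <- NULL
  perGroup <- do.call(rbind, lapply(
    split(perImage, perImage[, c("group", "type_a", "type_b")], drop = TRUE),
    function(s) data.frame(group = s$group[1], type_a = s$type_a[1],
                           type_b = s$type_b[1],
                           sum_sigval = sum(s$sigval), n_images = nrow(s),
                           mean_p_sum = mean(s$p_sum))))
  rownames(perGroup) <- NULL
  structure(list(perImage = perImage, perGroup = perGroup),
            class = "InteractionResult")
}
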