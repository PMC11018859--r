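# Proximity networks: undirected cell-type graphs whose edge lengths encode
# mean nearest-neighbor distance, edge widths encode 1/SD (x 100), with a
# heterogeneity-based width threshold, percent-total-binned node sizes and
# Louvain node clusters.

#' Build a proximity network for one group
#'
#' Symmetrizes the directed nearest-neighbor distance summary (arithmetic
#' mean of the two directed means and SDs), assigns edge widths
#' \code{widthConst / SD}, removes edges whose width falls below the
#' network's heterogeneity threshold (the width corresponding to the median
#' SD, times \code{cofactor}: an edge is dropped iff its SD exceeds
#' median(SD)/cofactor), bins node sizes from percent-total composition
#' (percent <= pctRange[1] maps to sizeRange[1], >= pctRange[2] to
#' sizeRange[2], monotone in 8 linear bins between), and clusters nodes by
#' Louvain community detection at the given resolution. A seeded
#' Fruchterman-Reingold layout with edge lengths proportional to mean
#' distance is attached for plotting.
#'
#' @param ds a \code{DistanceSummary} from \code{\link{nnDistances}}.
#' @param comp a composition table from \code{\link{composition}}.
#' @param group group to build the network for.
#' @param widthConst esthetic width constant (default 100).
#' @param cofactor network heterogeneity cofactor (default 0.8).
#' @param sizeRange node size endpoints (default 3 and 70).
#' @param pctRange percent-total endpoints mapped to sizeRange (1 and 25).
#' @param resolution Louvain resolution (default 1.5).
#' @param meanShannon optional mu-H' to attach (from
#'   \code{\link{shannonIndex}}).
#' @param seed seed for layout and clustering.
#' @return List of class \code{ProximityNetwork}: \code{nodes},
#'   \code{edges}, \code{graph} (igraph), \code{widthThreshold},
#'   \code{meanShannon}, \code{layout}.
#' @export
buildNetwork <- function(ds, comp, group = NULL, widthConst = 100,
                         cofactor = 0.8, sizeRange = c(3, 70),
                         pctRange = c(1, 25), resolution = 1.5,
                         meanShannon = NA_real_, seed = 1L) {
  s <- ds$summary
  if (!is.null(group)) s <- s[s$group == group, , drop = FALSE]
  comp <- comp[comp$region == "all", , drop = FALSE]
  if (!is.null(group)) comp <- comp[comp$group == group, , drop = FALSE]
  types <- sort(unique(c(s$type_a, s$type_b)))
  if (length(types) < 2L) stop("fewer than 2 cell types")

  # pooled percent-total per type across the group's images
  tot <- rowsum(comp$n, comp$cell_type)
  pct <- stats::setNames(100 * tot[, 1] / sum(tot), rownames(tot))[types]
  nodeSize <- binNodeSizes(pct, sizeRange, pctRange)

  # symmetrize ordered pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "||")
  s$pair <- key(s$type_a, s$type_b)
  edges <- do.call(rbind, lapply(split(s, s$pair), function(p) {
    data.frame(type_a = min(p$type_a[1], p$type_b[1]),
               type_b = max(p$type_a[1], p$type_b[1]),
               mean_dist = mean(p$mean), sd = mean(p$sd))
  }))
  rownames(edges) <- NULL
  edges <- edges[order(edges$type_a, edges$type_b), , drop = FALSE]
  edges$width <- widthConst / edges$sd
  medianSD <- stats::median(edges$sd, na.rm = TRUE)
  widthThreshold <- cofactor * widthConst / medianSD
  edges$kept <- is.finite(edges$width) & edges$width >= widthThreshold

  kept <- edges[edges$kept, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[, c("type_a", "type_b", "mean_dist", "sd", "width")],
    directed = FALSE,
    vertices = data.frame(name = types, percent = unname(pct),
                          size = unname(nodeSize)))
  set.seed(deriveSeed(seed, "louvain"))
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$width,
                                resolution = resolution)
  membership <- igraph::membership(cl)
  set.seed(deriveSeed(seed, "layout"))
  layout <- igraph::layout_with_fr(
    g, weights = 1 / pmax(igraph::E(g)$mean_dist, 1e-9))

  nodes <- data.frame(cell_type = types, percent = unname(pct),
                      node_size = unname(nodeSize),
                      cluster = as.integer(membership[types]))
  structure(list(nodes = nodes, edges = edges, graph = g,
                 widthThreshold = widthThreshold, medianSD = medianSD,
                 meanShannon = meanShannon, layout = layout),
            class = "ProximityNetwork")
}

# Monotone binned node sizes: <= lo% -> smallest, >= hi% -> largest,
# 8 linear bins between.
binNodeSizes <- function(pct, sizeRange = c(3, 70), pctRange = c(1, 25),
                         nBins = 8L) {
  sizes <- round(seq(sizeRange[1], sizeRange[2], length.out = nBins))
  breaks <- seq(pctRange[1], pctRange[2], length.out = nBins + 1L)
  idx <- findInterval(pct, breaks, rightmost.closed = FALSE)
  idx <- clamp(idx, 1L, nBins)
  out <- sizes[idx]
  out[pct <= pctRange[1]] <- sizes[1]
  out[pct >= pctRange[2]] <- sizes[nBins]
  stats::setNames(out, names(pct))
}

#' Export a proximity network as GraphML
#'
#' @param net a \code{ProximityNetwork}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNetworkGraphML <- function(net, path) {
  g <- net$graph
  igraph::V(g)$cluster <- net$nodes$cluster[match(igraph::V(g)$name,
                                                  net$nodes$cell_type)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
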