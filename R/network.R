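#' Item centrality from significance-filtered edges
#'
#' Centrality of an item is the inverted mean distance between the item and
#' all items it is connected to (its significant edges): well-connected items
#' with short distances to their neighbors are central. Items with no
#' significant edge are flagged isolated and placed at 0 on the inverted
#' scale (the minimum). A standardized (z) centrality is returned for ranked
#' bar plots.
#'
#' @param edges edge-test table from \code{\link{testEdges}}.
#' @param invert \code{"linear"} (default): centrality = \code{shift} - mean
#'   neighbor distance; \code{"reciprocal"}: 1 / mean neighbor distance.
#' @param shift shift of the linear inversion (default 2, an upper bound for
#'   typical normalized distances of standardized items).
#' @return data.frame: \code{item}, \code{meanNeighborDistance},
#'   \code{centrality}, \code{zCentrality}, \code{nNeighbors},
#'   \code{isolated}; ordered by the item's first appearance, invariant to
#'   input row order.
#' @export
itemCentrality <- function(edges, invert = c("linear", "reciprocal"),
                           shift = 2) {
  invert <- match.arg(invert)
  items <- sort(unique(c(edges$itemI, edges$itemJ)))
  sig <- edges[edges$significant, , drop = FALSE]
  md <- nn <- numeric(length(items))
  names(md) <- names(nn) <- items
  if (nrow(sig)) {
    acc <- rowsum(c(sig$meanDistance, sig$meanDistance),
                  c(sig$itemI, sig$itemJ))
    cnt <- rowsum(rep(1, 2L * nrow(sig)), c(sig$itemI, sig$itemJ))
    md[rownames(acc)] <- acc[, 1L] / cnt[, 1L]
    nn[rownames(cnt)] <- cnt[, 1L]
  }
  isolated <- nn == 0
  centrality <- ifelse(isolated, 0,
                       if (invert == "linear") shift - md else 1 / md)
  z <- if (stats::sd(centrality) > 0)
    as.vector(scale(centrality)) else rep(0, length(centrality))
  data.frame(item = items,
             meanNeighborDistance = ifelse(isolated, NA_real_, md),
             centrality = centrality,
             zCentrality = z,
             nNeighbors = as.integer(nn),
             isolated = isolated,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble a symptom network with fixed layout and edge scale
#'
#' Builds the group-level \linkS4class{SymptomNetwork} from the edge-test
#' results and item centralities. The whole-group call computes a seeded
#' Fruchterman-Reingold node placement and fixes the edge-effect range;
#' subgroup calls must pass the whole-group network as \code{layoutSource}
#' and inherit its coordinates and effect range bit-identically, so subgroup
#' plots are directly comparable (edge width, not node distance, carries the
#' association strength there).
#'
#' @param edges edge-test table from \code{\link{testEdges}}.
#' @param centralities result of \code{\link{itemCentrality}} (computed from
#'   \code{edges} when omitted).
#' @param catalog item catalog supplying scale color codes; defaults to the
#'   items present in \code{edges}.
#' @param layoutSource optional whole-group \linkS4class{SymptomNetwork}
#'   whose layout and effect range are reused; its node set must cover the
#'   current nodes.
#' @param seed seed for the layout (default 42); same seed, same coordinates.
#' @param group group label stored in the object.
#' @param frIterations Fruchterman-Reingold iteration cap (default 500).
#' @return A \linkS4class{SymptomNetwork}.
#' @export
buildNetwork <- function(edges, centralities = NULL, catalog = NULL,
                         layoutSource = NULL, seed = 42L, group = "all",
                         frIterations = 500L) {
  if (is.null(centralities)) centralities <- itemCentrality(edges)
  items <- centralities$item
  if (is.null(catalog)) {
    catalog <- data.frame(itemId = items, scale = NA_character_,
                          stringsAsFactors = FALSE)
  }
  nodes <- data.frame(item = items,
                      scale = catalog$scale[match(items, catalog$itemId)],
                      centrality = centralities$centrality,
                      zCentrality = centralities$zCentrality,
                      isolated = centralities$isolated,
                      stringsAsFactors = FALSE)
  sig <- edges[edges$significant, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = if (nrow(sig)) sig[, c("itemI", "itemJ", "effect", "pValue")] else
      data.frame(itemI = character(), itemJ = character(),
                 effect = numeric(), pValue = numeric()),
    directed = FALSE,
    vertices = data.frame(name = items, nodes[, -1L, drop = FALSE]))

  if (!is.null(layoutSource)) {
    stopifnot(methods::is(layoutSource, "SymptomNetwork"))
    missingNodes <- setdiff(items, rownames(layoutSource@layout))
    if (length(missingNodes))
      stop("layoutSource does not cover node(s): ",
           paste(utils::head(missingNodes, 5L), collapse = ", "))
    lay <- layoutSource@layout[items, , drop = FALSE]
    effectRange <- layoutSource@effectRange
  } else {
    set.seed(seed)
    w <- if (nrow(sig)) pmax(sig$effect - min(sig$effect) + 1e-6, 1e-6) else NULL
    lay <- igraph::layout_with_fr(g, weights = w, niter = frIterations)
    rownames(lay) <- items
    effectRange <- if (nrow(sig)) range(sig$effect) else c(0, 1)
  }
  nodes$x <- lay[, 1L]
  nodes$y <- lay[, 2L]
  methods::new("SymptomNetwork", nodes = nodes, edges = sig,
               layout = lay, alpha = attr(edges, "alpha") %||% NA_real_,
               group = group, effectRange = effectRange, graph = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a symptom network to tables, GraphML and JSON
#'
#' @param network a \linkS4class{SymptomNetwork}.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (default the group label).
#' @return Invisibly, the named vector of files written.
#' @export
exportNetwork <- function(network, dir, prefix = network@group) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    nodes = file.path(dir, paste0(prefix, "_nodes.csv")),
    edges = file.path(dir, paste0(prefix, "_edges.csv")),
    graphml = file.path(dir, paste0(prefix, "_network.graphml")),
    json = file.path(dir, paste0(prefix, "_network.json"))
  )
  utils::write.csv(network@nodes, files["nodes"], row.names = FALSE)
  utils::write.csv(network@edges, files["edges"], row.names = FALSE)
  igraph::write_graph(network@graph, files["graphml"], format = "graphml")
  jsonlite::write_json(
    list(group = network@group, alpha = network@alpha,
         effectRange = network@effectRange,
         nodes = network@nodes, edges = network@edges),
    files["json"], auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Plot a symptom network (fixed layout, centrality-sized nodes)
#'
#' @param x a \linkS4class{SymptomNetwork}.
#' @param y ignored.
#' @param ... passed to \code{plot.igraph}.
#' @export
setMethod("plot", signature(x = "SymptomNetwork", y = "missing"),
  function(x, y, ...) {
    g <- x@graph
    pal <- c(IDS = "#2c7fb8", BAI = "#d95f02", PSWQ = "#1b9e77")
    vcol <- pal[x@nodes$scale]
    vcol[is.na(vcol)] <- "grey60"
    size <- 4 + 10 * (x@nodes$centrality - min(x@nodes$centrality)) /
      max(1e-9, diff(range(x@nodes$centrality)))
    ew <- if (nrow(x@edges))
      0.5 + 4 * (x@edges$effect - x@effectRange[1L]) /
        max(1e-9, diff(x@effectRange)) else NULL
    igraph::plot.igraph(g, layout = x@layout, vertex.color = vcol,
                        vertex.size = size, vertex.label.cex = 0.5,
                        edge.width = ew, main = x@group, ...)
    invisible(x)
  })
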