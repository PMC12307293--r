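## Hierarchical structure of the communication network: prune weak edges,
## pick the root by weighted outdegree, layer nodes by BFS distance.

#' Prune weak edges
#'
#' Removes edges with weight strictly below `min_weight` (an edge exactly
#' at the threshold is kept). Nodes are never removed, so pruning can leave
#' isolated nodes.
#'
#' @param net a [CommNetwork-class].
#' @param min_weight pruning threshold (default 1e-4).
#' @return The pruned [CommNetwork-class]; the threshold is recorded in the
#'   network metadata.
#' @export
pruneEdges <- function(net, min_weight = 1e-4) {
  stopifnot(is(net, "CommNetwork"))
  .assertScalar(min_weight, "min_weight", min = 0)
  e <- networkEdges(net)
  e <- e[e$weight >= min_weight, , drop = FALSE]
  CommNetwork(e, nodes = networkNodes(net),
              pathways = net@pathways,
              metadata = c(net@metadata, list(prune_threshold = min_weight)))
}

#' Root node by weighted outdegree
#'
#' The root is the node whose outgoing edge weights sum highest; ties are
#' broken lexicographically by node name.
#'
#' @param net a [CommNetwork-class] with at least one node.
#' @return The root node name.
#' @export
findRoot <- function(net) {
  stopifnot(is(net, "CommNetwork"))
  nodes <- networkNodes(net)
  if (!length(nodes)) stop("network has no nodes")
  e <- networkEdges(net)
  outStrength <- setNames(rep(0, length(nodes)), nodes)
  if (nrow(e)) {
    s <- tapply(e$weight, e$from, sum)
    outStrength[names(s)] <- s
  }
  ord <- order(-outStrength, names(outStrength))
  names(outStrength)[ord[1]]
}

#' Layer nodes below a root
#'
#' Assigns each node its breadth-first distance from the root following
#' edge direction (root = layer 0); nodes unreachable from the root are
#' listed separately. The alternative `"longest_path"` rule assigns each
#' reachable node the length of the longest directed path from the root
#' and requires the reachable part to be acyclic.
#'
#' @param net a [CommNetwork-class].
#' @param root root node; defaults to [findRoot()].
#' @param rule `"bfs"` (default) or `"longest_path"`.
#' @return A [HierarchyLayout-class].
#' @examples
#' net <- CommNetwork(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                               weight = 1))
#' layerNodes(net, root = "A")
#' @export
layerNodes <- function(net, root = NULL, rule = c("bfs", "longest_path")) {
  stopifnot(is(net, "CommNetwork"))
  rule <- match.arg(rule)
  if (is.null(root)) root <- findRoot(net)
  nodes <- networkNodes(net)
  if (!root %in% nodes) stop("root '", root, "' is not a network node")
  g <- asIgraph(net)
  d <- igraph::distances(g, v = root, mode = "out", weights = NA)[1, ]
  reachable <- names(d)[is.finite(d)]
  if (rule == "longest_path") {
    sub <- igraph::induced_subgraph(g, reachable)
    if (!igraph::is_dag(sub))
      stop("longest-path layering requires the reachable subgraph to be acyclic")
    ord <- igraph::topo_sort(sub)$name
    lp <- setNames(rep(0, length(ord)), ord)
    for (v in ord) {
      preds <- igraph::neighbors(sub, v, mode = "in")$name
      if (length(preds)) lp[v] <- max(lp[preds]) + 1
    }
    layers <- lp[reachable]
  } else {
    layers <- d[reachable]
  }
  thr <- net@metadata$prune_threshold
  new("HierarchyLayout", root = root,
      layers = setNames(as.integer(layers), reachable),
      unreachable = setdiff(nodes, reachable),
      threshold = if (is.null(thr)) NA_real_ else thr)
}
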