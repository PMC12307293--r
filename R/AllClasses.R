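#' Labeled expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying a `counts` assay
#' (features in rows, cells/spots/samples in columns) and a mandatory
#' `label` column in `colData` giving the cell type, spot cluster or sample
#' group of each column. This is the common substrate for QC filtering,
#' marker ranking, communication scoring and signature scoring.
#'
#' @slot unit character; what the columns are ("cell", "spot" or "sample").
#' @export
setClass("LabeledExpression",
  contains = "SummarizedExperiment",
  representation(unit = "character"))

setValidity("LabeledExpression", function(object) {
  msg <- NULL
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  if (!"label" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'label' is required")
  if (!object@unit %in% c("cell", "spot", "sample"))
    msg <- c(msg, "unit must be one of 'cell', 'spot', 'sample'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LabeledExpression object
#'
#' @param counts feature-by-column matrix (dense or sparse) of non-negative
#'   expression values; integer counts for single-cell/spot data.
#' @param labels character or factor, one group label per column.
#' @param unit what a column is: `"cell"`, `"spot"` or `"sample"`.
#' @param ... further arguments passed to the
#'   `SummarizedExperiment` constructor (e.g. `rowData`, `metadata`).
#' @return A [LabeledExpression-class] object.
#' @examples
#' m <- matrix(rpois(50, 2), nrow = 10,
#'             dimnames = list(paste0("G", 1:10), paste0("c", 1:5)))
#' le <- LabeledExpression(m, labels = c("A", "A", "B", "B", "B"))
#' cellLabels(le)
#' @export
LabeledExpression <- function(counts, labels, unit = "cell", ...) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("%s%05d", substr(unit, 1, 1), seq_len(ncol(counts)))
  if (length(labels) != ncol(counts))
    stop("'labels' must have one entry per column of 'counts'")
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(label = as.character(labels), row.names = colnames(counts)),
    ...)
  new("LabeledExpression", se, unit = unit)
}

#' @describeIn LabeledExpression column group labels.
#' @param x a `LabeledExpression` object.
#' @export
cellLabels <- function(x) {
  stopifnot(is(x, "LabeledExpression"))
  as.character(colData(x)$label)
}

#' Weighted directed cell-type communication network
#'
#' Nodes are cell types; a directed edge s -> r carries the aggregated
#' ligand-receptor communication strength from sender s to receiver r.
#' Autocrine (self-loop) edges are permitted in the network itself; the
#' motif census excludes and reports them separately.
#'
#' @slot nodes character vector of unique node (cell type) names.
#' @slot edges data.frame with columns `from`, `to`, `weight` (>= 0).
#' @slot pathways optional per-pathway edge breakdown (`from`, `to`,
#'   `pathway`, `weight`) or NULL.
#' @slot metadata list of provenance fields (pruning threshold, config).
#' @export
setClass("CommNetwork",
  representation(nodes = "character", edges = "data.frame",
                 pathways = "ANY", metadata = "list"))

setValidity("CommNetwork", function(object) {
  msg <- NULL
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% colnames(e)))
    msg <- c(msg, "edges need columns from, to, weight")
  else {
    if (anyDuplicated(object@nodes)) msg <- c(msg, "node names must be unique")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed nodes")
    if (any(!is.finite(e$weight)) || any(e$weight < 0))
      msg <- c(msg, "edge weights must be finite and >= 0")
    if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
      msg <- c(msg, "duplicate directed edges are not allowed")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CommNetwork
#'
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param nodes optional character vector of nodes; defaults to the union of
#'   edge endpoints (isolated nodes must be passed explicitly).
#' @param pathways optional data.frame (`from`, `to`, `pathway`, `weight`).
#' @param metadata list of provenance fields.
#' @return A [CommNetwork-class].
#' @examples
#' net <- CommNetwork(data.frame(from = "A", to = "B", weight = 0.5),
#'                    nodes = c("A", "B", "C"))
#' networkNodes(net)
#' @export
CommNetwork <- function(edges, nodes = NULL, pathways = NULL, metadata = list()) {
  edges <- as.data.frame(edges)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  new("CommNetwork", nodes = as.character(nodes), edges = edges,
      pathways = pathways, metadata = metadata)
}

#' @describeIn CommNetwork node names.
#' @param x a `CommNetwork`.
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn CommNetwork edge list (`from`, `to`, `weight`).
#' @export
networkEdges <- function(x) x@edges

#' @describeIn CommNetwork dense weighted adjacency matrix (senders in rows).
#' @export
adjacencyMatrix <- function(x) {
  n <- length(x@nodes)
  A <- matrix(0, n, n, dimnames = list(x@nodes, x@nodes))
  if (nrow(x@edges))
    A[cbind(x@edges$from, x@edges$to)] <- x@edges$weight
  A
}

#' @describeIn CommNetwork convert to an igraph object (weights as the
#'   `weight` edge attribute).
#' @export
asIgraph <- function(x) {
  igraph::graph_from_data_frame(x@edges, directed = TRUE,
                                vertices = data.frame(name = x@nodes))
}

#' Motif census of a directed network
#'
#' Per-isomorphism-class counts and summed edge-weight strengths for all
#' weakly-connected induced subgraphs on 2-4 nodes.
#'
#' @slot table data.frame: `class_id`, `size`, `count`, `strength`, `alias`.
#' @slot sizes integer vector of the subgraph sizes censused.
#' @slot instances optional per-instance table (`nodes`, `class_id`,
#'   `strength`) or NULL when not retained.
#' @slot metadata list (e.g. number of self-loops excluded).
#' @export
setClass("MotifCensus",
  representation(table = "data.frame", sizes = "integer",
                 instances = "ANY", metadata = "list"))

setValidity("MotifCensus", function(object) {
  t <- object@table
  if (!all(c("class_id", "size", "count", "strength") %in% colnames(t)))
    return("table needs columns class_id, size, count, strength")
  if (nrow(t) && (any(t$count < 0) || any(t$strength < -1e-12)))
    return("counts and strengths must be non-negative")
  TRUE
})

#' @describeIn MotifCensus the per-class census table.
#' @param x a `MotifCensus`.
#' @export
censusTable <- function(x) x@table

#' @describeIn MotifCensus the per-instance table (NULL unless retained).
#' @export
motifInstances <- function(x) x@instances

#' Null-ensemble motif significance statistics
#'
#' For every motif class: the observed count and sum-strength statistic,
#' the null mean and standard deviation over degree-preserving rewired
#' networks, z-scores and upper-tail empirical p-values with add-one
#' smoothing. z is NA when the null standard deviation is zero.
#'
#' @slot stats data.frame, one row per motif class.
#' @slot nRandom number of null networks used.
#' @slot metadata list (config echo, seed).
#' @export
setClass("NullEnsembleStats",
  representation(stats = "data.frame", nRandom = "integer", metadata = "list"))

#' @describeIn NullEnsembleStats the per-class statistics table.
#' @param x a `NullEnsembleStats`.
#' @export
nullStats <- function(x) x@stats

#' Samples-by-signatures score matrix
#'
#' @slot scores numeric matrix, rows = samples (or cells/spots), columns =
#'   signatures.
#' @slot method which scorer produced it ("module", "auc", "ssgsea").
#' @slot normalization normalization tag ("none", "range").
#' @export
setClass("ScoreMatrix",
  representation(scores = "matrix", method = "character",
                 normalization = "character"))

setValidity("ScoreMatrix", function(object) {
  if (length(object@scores) && any(!is.finite(object@scores)))
    return("scores must be finite")
  if (is.null(colnames(object@scores)))
    return("score columns must be named by signature")
  TRUE
})

#' @describeIn ScoreMatrix the numeric score matrix.
#' @param x a `ScoreMatrix`.
#' @export
scoreValues <- function(x) x@scores

#' Hierarchical layout of a communication network
#'
#' @slot root root node (highest weighted outdegree).
#' @slot layers named integer vector: BFS distance from the root, root = 0.
#' @slot unreachable nodes not reachable from the root along edge direction.
#' @slot threshold edge-pruning threshold in force when laid out (NA if none).
#' @export
setClass("HierarchyLayout",
  representation(root = "character", layers = "integer",
                 unreachable = "character", threshold = "numeric"))

setValidity("HierarchyLayout", function(object) {
  if (length(object@layers)) {
    if (is.na(object@layers[object@root]) || object@layers[object@root] != 0L)
      return("root must be assigned layer 0")
    if (any(object@layers < 0L)) return("layers must be non-negative")
  }
  TRUE
})

#' Tumor-microenvironment cluster assignment
#'
#' @slot clusters named integer vector: sample -> cluster id.
#' @slot k the number of clusters chosen.
#' @slot centroids k-by-signature matrix of mean (scaled) scores.
#' @slot subtypeLabels named character vector: cluster id -> semantic label.
#' @slot silhouette mean silhouette width at the chosen k.
#' @slot weakStructure TRUE when mean silhouette < 0.25.
#' @slot metadata list (config echo, per-k criterion trace).
#' @export
setClass("TMEAssignment",
  representation(clusters = "integer", k = "integer", centroids = "matrix",
                 subtypeLabels = "character", silhouette = "numeric",
                 weakStructure = "logical", metadata = "list"))

#' @describeIn TMEAssignment sample -> cluster id.
#' @param x a `TMEAssignment`.
#' @export
clusterAssignments <- function(x) x@clusters

#' @describeIn TMEAssignment sample -> semantic subtype label (available
#'   after [labelSubtypes()]).
#' @export
sampleSubtypes <- function(x) {
  if (!length(x@subtypeLabels)) stop("run labelSubtypes() first")
  setNames(x@subtypeLabels[as.character(x@clusters)], names(x@clusters))
}
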