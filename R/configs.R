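## Validated parameter objects (plain classed lists, one constructor each).

#' Quality-control thresholds
#'
#' Boundary semantics follow the source conventions exactly: cells with
#' library size <= `min_umi_exclusive` or mitochondrial fraction >=
#' `max_mito_frac_exclusive` are excluded; genes detected in fewer than
#' `min_cells_per_gene` cells are removed (a gene in exactly that many cells
#' is kept).
#'
#' @param min_umi_exclusive cells at or below this UMI total are dropped.
#' @param max_mito_frac_exclusive cells at or above this mitochondrial
#'   fraction are dropped.
#' @param min_cells_per_gene genes detected in fewer cells are removed.
#' @param min_genes_per_spot spots with fewer detected genes are removed.
#' @param min_counts_per_gene_spatial spatial genes with a lower total count
#'   are removed.
#' @param min_spots_per_gene spatial genes detected in fewer spots are removed.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return A `qc_thresholds` list.
#' @export
qcThresholds <- function(min_umi_exclusive = 2000,
                         max_mito_frac_exclusive = 0.05,
                         min_cells_per_gene = 3,
                         min_genes_per_spot = 200,
                         min_counts_per_gene_spatial = 10,
                         min_spots_per_gene = 3,
                         mito_prefix = "MT-") {
  .assertScalar(min_umi_exclusive, "min_umi_exclusive", min = 0)
  .assertScalar(max_mito_frac_exclusive, "max_mito_frac_exclusive", 0, 1)
  .assertScalar(min_cells_per_gene, "min_cells_per_gene", min = 0, integer = TRUE)
  .assertScalar(min_genes_per_spot, "min_genes_per_spot", min = 0, integer = TRUE)
  .assertScalar(min_counts_per_gene_spatial, "min_counts_per_gene_spatial", min = 0)
  .assertScalar(min_spots_per_gene, "min_spots_per_gene", min = 0, integer = TRUE)
  structure(list(min_umi_exclusive = min_umi_exclusive,
                 max_mito_frac_exclusive = max_mito_frac_exclusive,
                 min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_spot = min_genes_per_spot,
                 min_counts_per_gene_spatial = min_counts_per_gene_spatial,
                 min_spots_per_gene = min_spots_per_gene,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Marker-selection criteria (top-30 rule)
#'
#' @param max_adj_p keep genes with BH-adjusted p at or below this.
#' @param min_avg_logfc keep genes with average log2 fold change at or above
#'   this (positive markers only).
#' @param top_n signature length cap per cell type.
#' @return A `marker_criteria` list.
#' @export
markerCriteria <- function(max_adj_p = 0.05, min_avg_logfc = 0.15, top_n = 30) {
  .assertScalar(max_adj_p, "max_adj_p", 1e-300, 1)
  .assertScalar(min_avg_logfc, "min_avg_logfc")
  .assertScalar(top_n, "top_n", min = 1, integer = TRUE)
  structure(list(max_adj_p = max_adj_p, min_avg_logfc = min_avg_logfc,
                 top_n = as.integer(top_n)),
            class = "marker_criteria")
}

#' Communication-scoring configuration
#'
#' The strength of a ligand-receptor pair from sender s to receiver r is a
#' saturating mass-action score (L*R) / (hill_k + L*R), with L and R
#' trimmed-mean log-normalized expression (geometric mean over subunits).
#' Cell types with fewer than `min_cells` cells contribute no interactions.
#'
#' @param min_cells minimum cells per participating type.
#' @param hill_k half-saturation constant of the Hill score.
#' @param trim_frac fraction trimmed from each tail of the expression mean.
#' @return A `comm_config` list.
#' @export
commConfig <- function(min_cells = 5, hill_k = 0.5, trim_frac = 0.1) {
  .assertScalar(min_cells, "min_cells", min = 1, integer = TRUE)
  .assertScalar(hill_k, "hill_k", min = 1e-12)
  .assertScalar(trim_frac, "trim_frac", 0, 0.45)
  structure(list(min_cells = as.integer(min_cells), hill_k = hill_k,
                 trim_frac = trim_frac),
            class = "comm_config")
}

#' Null-ensemble configuration for motif significance
#'
#' @param n_random number of rewired networks (the reference procedure used
#'   50,000; the desk-scale default is 1,000).
#' @param swaps_per_edge attempted double-edge swaps per edge for each draw.
#' @param seed RNG seed for the ensemble.
#' @param statistic which statistic(s) to test: `"count"`, `"strength"`, or
#'   `"both"`.
#' @param weight_mode `"ride"` (weights travel with swapped arcs; default)
#'   or `"shuffle"` (weights reassigned uniformly at random after rewiring).
#' @param tail `"upper"` (enrichment, default) or `"two.sided"`.
#' @return A `null_config` list.
#' @export
nullConfig <- function(n_random = 1000, swaps_per_edge = 10, seed = 1,
                       statistic = c("both", "count", "strength"),
                       weight_mode = c("ride", "shuffle"),
                       tail = c("upper", "two.sided")) {
  .assertScalar(n_random, "n_random", min = 1, integer = TRUE)
  .assertScalar(swaps_per_edge, "swaps_per_edge", min = 1e-9)
  .assertScalar(seed, "seed", integer = TRUE)
  structure(list(n_random = as.integer(n_random), swaps_per_edge = swaps_per_edge,
                 seed = as.integer(seed), statistic = match.arg(statistic),
                 weight_mode = match.arg(weight_mode), tail = match.arg(tail)),
            class = "null_config")
}

#' Single-sample GSEA configuration
#'
#' @param alpha exponent weighting in-set ranks (rank^alpha).
#' @param normalize divide each signature's scores by its max - min across
#'   samples.
#' @return A `ssgsea_config` list.
#' @export
ssgseaConfig <- function(alpha = 0.25, normalize = TRUE) {
  .assertScalar(alpha, "alpha", min = 0)
  structure(list(alpha = alpha, normalize = isTRUE(normalize)),
            class = "ssgsea_config")
}

#' Clustering configuration for TME subtyping
#'
#' @param method `"ward"` (hierarchical, Ward.D2 on Euclidean distance) or
#'   `"kmeans"`.
#' @param k_min,k_max candidate cluster-number range (defaults 2..10).
#' @param selection model-selection rule: mean `"silhouette"` (default),
#'   `"gap"` statistic, or `"fixed_k"` (use `k_fixed`).
#' @param k_fixed the k to use when `selection = "fixed_k"`.
#' @param n_init random restarts for k-means.
#' @param seed RNG seed (k-means restarts, gap reference draws).
#' @param scaling `"zscore"` (per-signature standardization; default) or
#'   `"none"`.
#' @return A `cluster_config` list.
#' @export
clusterConfig <- function(method = c("ward", "kmeans"), k_min = 2, k_max = 10,
                          selection = c("silhouette", "gap", "fixed_k"),
                          k_fixed = NULL, n_init = 25, seed = 1,
                          scaling = c("zscore", "none")) {
  method <- match.arg(method)
  selection <- match.arg(selection)
  .assertScalar(k_min, "k_min", min = 2, integer = TRUE)
  .assertScalar(k_max, "k_max", min = k_min, integer = TRUE)
  .assertScalar(n_init, "n_init", min = 1, integer = TRUE)
  .assertScalar(seed, "seed", integer = TRUE)
  if (selection == "fixed_k") {
    if (is.null(k_fixed)) stop("selection = 'fixed_k' requires k_fixed")
    .assertScalar(k_fixed, "k_fixed", min = 2, integer = TRUE)
    k_fixed <- as.integer(k_fixed)
  }
  structure(list(method = method, k_min = as.integer(k_min),
                 k_max = as.integer(k_max), selection = selection,
                 k_fixed = k_fixed, n_init = as.integer(n_init),
                 seed = as.integer(seed), scaling = match.arg(scaling)),
            class = "cluster_config")
}
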