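## Unsupervised tumor-microenvironment subtyping from barrier-associated
## signature scores, and semantic labeling of the resulting clusters.

#' @noRd
.clusterOnce <- function(X, k, method, n_init) {
  if (method == "kmeans") {
    stats::kmeans(X, centers = k, nstart = n_init, iter.max = 100)$cluster
  } else {
    hc <- stats::hclust(dist(X), method = "ward.D2")
    stats::cutree(hc, k = k)
  }
}

#' Cluster samples on signature scores
#'
#' Scores are standardized per signature (when configured), clustered for
#' every k in `[k_min, k_max]` by Ward-linkage hierarchical clustering
#' (Ward.D2 merge criterion on Euclidean distance) or k-means with random
#' restarts, and the k maximizing the model-selection criterion (mean
#' silhouette width by default, gap statistic optionally) is chosen.
#' `selection = "fixed_k"` bypasses selection. A mean silhouette below
#' 0.25 at the chosen k raises the `weakStructure` flag.
#'
#' @param scores a [ScoreMatrix-class] (samples x signatures).
#' @param config a [clusterConfig()].
#' @return A [TMEAssignment-class].
#' @export
clusterScores <- function(scores, config = clusterConfig()) {
  stopifnot(is(scores, "ScoreMatrix"), inherits(config, "cluster_config"))
  X <- scoreValues(scores)
  const <- apply(X, 2, function(x) sd(x) == 0)
  if (any(const)) {
    warning("dropping constant score column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (!ncol(X)) stop("no informative score columns")
  if (config$scaling == "zscore") X <- scale(X)
  n <- nrow(X)
  kMax <- config$k_max
  if (n <= kMax) {
    kMax <- n - 1L
    warning("fewer samples than k_max + 1; lowering k_max to ", kMax)
  }
  set.seed(config$seed)
  d <- dist(X)
  meanSil <- function(cl) mean(cluster::silhouette(cl, d)[, "sil_width"])
  if (config$selection == "fixed_k") {
    k <- min(config$k_fixed, kMax)
    cl <- .clusterOnce(X, k, config$method, config$n_init)
    trace <- data.frame(k = k, criterion = meanSil(cl))
  } else {
    ks <- config$k_min:kMax
    cls <- lapply(ks, function(k) .clusterOnce(X, k, config$method, config$n_init))
    crit <- if (config$selection == "silhouette") {
      vapply(cls, meanSil, numeric(1))
    } else {
      gap <- cluster::clusGap(X, FUNcluster = function(x, k)
        list(cluster = .clusterOnce(x, k, config$method, config$n_init)),
        K.max = kMax, B = 25, verbose = FALSE)
      gap$Tab[ks, "gap"]
    }
    best <- which.max(crit)
    k <- ks[best]
    cl <- cls[[best]]
    trace <- data.frame(k = ks, criterion = crit)
  }
  cl <- setNames(as.integer(cl), rownames(X))
  sil <- meanSil(cl)
  centroids <- do.call(rbind, lapply(sort(unique(cl)), function(g)
    colMeans(X[cl == g, , drop = FALSE])))
  rownames(centroids) <- sort(unique(cl))
  new("TMEAssignment", clusters = cl, k = as.integer(k),
      centroids = centroids, subtypeLabels = character(0),
      silhouette = sil, weakStructure = sil < 0.25,
      metadata = list(config = config, selection_trace = trace))
}

#' Semantic subtype labels from barrier and exhaustion indices
#'
#' Each cluster gets a barrier index (mean centroid over the barrier
#' signatures) and an exhaustion index (mean centroid over the exhaustion
#' signatures). Median-splitting both indices across clusters yields the
#' four canonical tumor-microenvironment patterns:
#' high/high = `barrier_with_exhaustion`, high/low = `barrier_dominant`,
#' low/high = `exhaustion_dominant`, low/low = `desert`.
#' Labels depend only on the centroids, so they are invariant to cluster
#' id permutation.
#'
#' @param assign a [TMEAssignment-class] from [clusterScores()].
#' @param barrier_sigs,exhaustion_sigs signature (column) names defining
#'   the two indices; must be present among the clustered scores.
#' @return The [TMEAssignment-class] with `subtypeLabels` filled in;
#'   per-sample labels via [sampleSubtypes()].
#' @export
labelSubtypes <- function(assign, barrier_sigs, exhaustion_sigs) {
  stopifnot(is(assign, "TMEAssignment"))
  cn <- colnames(assign@centroids)
  missing <- setdiff(c(barrier_sigs, exhaustion_sigs), cn)
  if (length(missing))
    stop("signature(s) absent from the score columns: ",
         paste(missing, collapse = ", "))
  bi <- rowMeans(assign@centroids[, barrier_sigs, drop = FALSE])
  ei <- rowMeans(assign@centroids[, exhaustion_sigs, drop = FALSE])
  bHigh <- bi > median(bi)
  eHigh <- ei > median(ei)
  lab <- ifelse(bHigh & eHigh, "barrier_with_exhaustion",
         ifelse(bHigh & !eHigh, "barrier_dominant",
         ifelse(!bHigh & eHigh, "exhaustion_dominant", "desert")))
  assign@subtypeLabels <- setNames(lab, rownames(assign@centroids))
  assign@metadata$indices <- data.frame(cluster = rownames(assign@centroids),
                                        barrier = bi, exhaustion = ei)
  assign
}
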