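## Exact enumeration of connected induced subgraph motifs, sizes 2-4.
## Every k-node subset is visited once; its induced adjacency is packed into
## a bit code and classified through the precomputed canonical-code table,
## so the inner work per subset is a handful of vectorized index lookups.

## census core on an integer-indexed adjacency/weight pair; returns per-class
## counts and strengths aligned to .connectedClasses(k)
#' @noRd
.censusSize <- function(A, W, k, keep_instances = FALSE) {
  classes <- .connectedClasses(k)
  n <- nrow(A)
  res <- list(count = setNames(numeric(nrow(classes)), classes$class_id),
              strength = setNames(numeric(nrow(classes)), classes$class_id),
              instances = NULL)
  if (n < k) return(res)
  tab <- .codeTable(k)
  combs <- combn(n, k)
  m <- tab$m
  codes <- numeric(ncol(combs))
  strengths <- numeric(ncol(combs))
  for (j in seq_len(m)) {
    u <- combs[tab$pairs[j, 1], ]
    v <- combs[tab$pairs[j, 2], ]
    idx <- cbind(u, v)
    codes <- codes + A[idx] * 2^(m - j)
    strengths <- strengths + W[idx]
  }
  keep <- tab$conn[codes + 1]
  if (any(keep)) {
    cc <- tab$canon[codes[keep] + 1]
    pos <- match(cc, classes$code)
    cnt <- tabulate(pos, nbins = nrow(classes))
    str <- rowsum(strengths[keep], pos)
    res$count[] <- cnt
    res$strength[as.integer(rownames(str))] <- str[, 1]
    if (keep_instances) {
      ks <- which(keep)
      res$instances <- data.frame(
        nodes = apply(combs[, ks, drop = FALSE], 2, paste, collapse = ","),
        class_id = classes$class_id[pos],
        strength = strengths[keep],
        stringsAsFactors = FALSE)
    }
  }
  res
}

## strip self-loops, return integer adjacency + weight matrices
#' @noRd
.networkMatrices <- function(net) {
  W <- adjacencyMatrix(net)
  nSelf <- sum(diag(W) != 0)
  diag(W) <- 0
  list(A = (W != 0) * 1L, W = W, nSelf = nSelf,
       selfLoops = net@edges[net@edges$from == net@edges$to, , drop = FALSE])
}

#' Enumerate connected induced motifs of a communication network
#'
#' Counts every weakly-connected induced subgraph on 2, 3 and/or 4 nodes of
#' a simple weighted digraph, classifies each by directed-isomorphism class,
#' and records the per-class instance count and total strength (sum of
#' induced edge weights over instances). Each node set is counted exactly
#' once. Self-loops are excluded from the census and reported in the result
#' metadata.
#'
#' @param net a [CommNetwork-class].
#' @param sizes subset of `c(2, 3, 4)`.
#' @param keep_instances retain the per-instance table (node sets and
#'   strengths); off by default.
#' @return A [MotifCensus-class]. The census table lists every connected
#'   isomorphism class of the requested sizes, including classes with zero
#'   observed instances.
#' @examples
#' net <- CommNetwork(data.frame(from = c("A", "B", "C"),
#'                               to   = c("B", "C", "A"),
#'                               weight = c(0.1, 0.2, 0.3)))
#' censusTable(enumerateMotifs(net, sizes = 3))
#' @export
enumerateMotifs <- function(net, sizes = c(2, 3, 4), keep_instances = FALSE) {
  stopifnot(is(net, "CommNetwork"))
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) == 0 || any(!sizes %in% 2:4))
    stop("'sizes' must be a non-empty subset of {2, 3, 4}")
  mats <- .networkMatrices(net)
  if (mats$nSelf > 0)
    message(mats$nSelf, " self-loop(s) excluded from the motif census")
  tabs <- vector("list", length(sizes))
  inst <- list()
  for (i in seq_along(sizes)) {
    k <- sizes[i]
    r <- .censusSize(mats$A, mats$W, k, keep_instances)
    cls <- .connectedClasses(k)
    tabs[[i]] <- data.frame(class_id = cls$class_id, size = k,
                            count = as.numeric(r$count),
                            strength = as.numeric(r$strength),
                            alias = cls$alias, stringsAsFactors = FALSE)
    if (!is.null(r$instances)) inst[[length(inst) + 1]] <- r$instances
  }
  new("MotifCensus",
      table = do.call(rbind, tabs), sizes = sizes,
      instances = if (keep_instances) do.call(rbind, inst) else NULL,
      metadata = list(n_self_loops = mats$nSelf, self_loops = mats$selfLoops,
                      n_nodes = length(networkNodes(net))))
}

#' Top motif classes by total strength
#'
#' Ranks motif classes by total strength (descending), breaking ties by
#' instance count then class id, and returns the leading classes. Classes
#' with zero instances are dropped before ranking.
#'
#' @param census a [MotifCensus-class].
#' @param n how many classes to return (all, if fewer exist).
#' @param size optionally restrict to one subgraph size.
#' @return data.frame of the top classes.
#' @export
topMotifs <- function(census, n = 4, size = NULL) {
  stopifnot(is(census, "MotifCensus"))
  .assertScalar(n, "n", min = 1, integer = TRUE)
  t <- censusTable(census)
  if (!is.null(size)) t <- t[t$size %in% size, , drop = FALSE]
  t <- t[t$count > 0, , drop = FALSE]
  t <- t[order(-t$strength, -t$count, t$class_id), , drop = FALSE]
  head(t, n)
}
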