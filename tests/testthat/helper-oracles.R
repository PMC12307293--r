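## Independent oracles and fixture builders used across the suite.
## These deliberately use naive loops / direct permutation of adjacency
## matrices rather than the package's lookup-table code paths.

suppressPackageStartupMessages({
  library(Matrix)
  library(SummarizedExperiment)
})

## all permutations of 1..k, as a list (naive recursion)
permsOf <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in permsOf(k - 1)) {
    for (pos in 0:(k - 1)) out[[length(out) + 1]] <- append(p, k, after = pos)
  }
  out
}

## canonical key of a small adjacency matrix by direct permutation:
## minimum over all node orders of the row-major 0/1 string
oracleKey <- function(adj) {
  k <- nrow(adj)
  best <- NULL
  for (p in permsOf(k)) {
    s <- paste(ifelse(adj[p, p][!diag(k) > 0], 1, 0), collapse = "")
    if (is.null(best) || s < best) best <- s
  }
  best
}

## weak connectivity by repeated neighbor expansion on the symmetrized matrix
oracleConnected <- function(adj) {
  k <- nrow(adj)
  u <- (adj | t(adj))
  reach <- c(TRUE, rep(FALSE, k - 1))
  for (i in seq_len(k)) reach <- reach | (u %*% reach > 0)[, 1]
  all(reach)
}

## brute-force census: iterate every k-subset of nodes, keep weakly
## connected induced subgraphs, group by oracleKey, sum weights
oracleCensus <- function(W, k) {
  n <- nrow(W)
  groups <- list()
  if (n >= k) {
    subs <- utils::combn(n, k)
    for (i in seq_len(ncol(subs))) {
      sel <- subs[, i]
      sub <- W[sel, sel, drop = FALSE]
      adj <- sub != 0
      diag(adj) <- FALSE
      if (!oracleConnected(adj)) next
      key <- oracleKey(adj)
      st <- sum(sub[adj])
      if (is.null(groups[[key]])) {
        groups[[key]] <- list(count = 1L, strength = st, rep = adj * 1L)
      } else {
        groups[[key]]$count <- groups[[key]]$count + 1L
        groups[[key]]$strength <- groups[[key]]$strength + st
      }
    }
  }
  groups
}

## naive single-sample GSEA running sum, one sample at a time
oracleSsgsea <- function(X, sets, alpha = 0.25, normalize = TRUE) {
  out <- matrix(0, ncol(X), length(sets),
                dimnames = list(colnames(X), names(sets)))
  for (s in seq_len(ncol(X))) {
    r <- rank(X[, s])
    ord <- order(-r, rownames(X))    # ties walked in gene-name order
    for (j in seq_along(sets)) {
      ins <- rownames(X)[ord] %in% sets[[j]]
      sumIn <- 0
      sumInTotal <- sum(r[rownames(X) %in% sets[[j]]]^alpha)
      nOut <- sum(!ins)
      cumOut <- 0
      es <- 0
      for (i in seq_along(ord)) {
        if (ins[i]) sumIn <- sumIn + r[ord[i]]^alpha else cumOut <- cumOut + 1
        es <- es + sumIn / sumInTotal - cumOut / nOut
      }
      out[s, j] <- es
    }
  }
  if (normalize)
    for (j in seq_len(ncol(out))) {
      rng <- max(out[, j]) - min(out[, j])
      if (rng > 0) out[, j] <- out[, j] / rng
    }
  out
}

## naive AUC recovery-curve score for one expression vector
oracleAucScore <- function(x, shuffle, sigIdx, top_frac) {
  G <- length(x)
  maxRank <- ceiling(top_frac * G)
  ord <- order(-x, shuffle)
  rk <- match(seq_len(G), ord)
  hits <- function(at) sum(rk[sigIdx] <= at)
  auc <- sum(vapply(seq_len(maxRank), hits, numeric(1)))
  maxAuc <- sum(vapply(seq_len(maxRank), function(a) min(a, length(sigIdx)),
                       numeric(1)))
  auc / maxAuc
}

## random Erdos-Renyi weighted digraph as a CommNetwork
randomNet <- function(n, p, wfun = function(m) rlnorm(m, -1, 0.5)) {
  A <- matrix(runif(n * n) < p, n, n)
  diag(A) <- FALSE
  idx <- which(A, arr.ind = TRUE)
  nodes <- sprintf("N%02d", seq_len(n))
  edges <- if (nrow(idx)) {
    data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
               weight = wfun(nrow(idx)), stringsAsFactors = FALSE)
  } else data.frame(from = character(), to = character(), weight = numeric())
  CommNetwork(edges, nodes = nodes)
}

## degree sequences of a CommNetwork as a canonical string (for comparisons)
degreeSignature <- function(net) {
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  paste(c(tabulate(match(e$from, nodes), length(nodes)),
          tabulate(match(e$to, nodes), length(nodes))), collapse = ",")
}

## small labeled expression fixture with hand-set columns
makeExpr <- function(counts, labels, unit = "cell") {
  LabeledExpression(counts, labels = labels, unit = unit)
}

## compare a package census with the subset oracle, class by class
expectCensusMatchesOracle <- function(net, sizes = c(2, 3, 4)) {
  cen <- censusTable(suppressMessages(enumerateMotifs(net, sizes)))
  W <- adjacencyMatrix(net)
  diag(W) <- 0
  for (k in sizes) {
    groups <- oracleCensus(W, k)
    ids <- vapply(groups, function(g) canonicalClass(g$rep)$id, character(1))
    oc <- data.frame(class_id = unname(ids),
                     count = vapply(groups, `[[`, numeric(1), "count"),
                     strength = vapply(groups, `[[`, numeric(1), "strength"))
    tk <- cen[cen$size == k, ]
    for (i in seq_len(nrow(oc))) {
      row <- tk[tk$class_id == oc$class_id[i], ]
      expect_equal(row$count, oc$count[i])
      expect_equal(row$strength, oc$strength[i], tolerance = 1e-10)
    }
    expect_equal(sum(tk$count), sum(oc$count))
    expect_equal(sum(tk$strength), sum(oc$strength), tolerance = 1e-10)
  }
}
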