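## Signature scoring: expression-bin-controlled module scores for cells or
## spots, AUC recovery-curve scores, and single-sample GSEA for bulk data.

#' @noRd
.asSignatureList <- function(sig) {
  s <- unclass(sig)
  attributes(s) <- list(names = names(s))
  if (is.null(names(s)) || any(names(s) == ""))
    stop("signatures must be a named list of gene vectors")
  s
}

#' Control-bin module score
#'
#' Per cell (or spot): mean log-normalized expression of the signature
#' genes minus the mean of control genes. Genes are binned into `n_bins`
#' groups of similar dataset-wide average expression and `n_ctrl` controls
#' are drawn (per signature gene) from the gene's bin, so the control set
#' is expression-matched.
#'
#' @param expr a [LabeledExpression-class].
#' @param sigs named list of gene vectors (or [rankMarkers()] output).
#' @param n_bins number of average-expression bins.
#' @param n_ctrl control genes drawn per signature gene.
#' @param seed RNG seed for the control draws.
#' @return A [ScoreMatrix-class], cells in rows.
#' @export
moduleScore <- function(expr, sigs, n_bins = 24, n_ctrl = 100, seed = 1) {
  stopifnot(is(expr, "LabeledExpression"))
  sigs <- .asSignatureList(sigs)
  .assertScalar(n_bins, "n_bins", min = 2, integer = TRUE)
  .assertScalar(n_ctrl, "n_ctrl", min = 1, integer = TRUE)
  ln <- .asDense(.cp10kLog(assay(expr, "counts")))
  if (nrow(ln) < n_bins)
    stop("need at least 'n_bins' genes")
  avg <- rowMeans(ln)
  bin <- as.integer(cut(rank(avg, ties.method = "first"), breaks = n_bins))
  set.seed(seed)
  out <- matrix(NA_real_, ncol(ln), length(sigs),
                dimnames = list(colnames(ln), names(sigs)))
  for (j in seq_along(sigs)) {
    genes <- intersect(sigs[[j]], rownames(ln))
    if (!length(genes))
      stop("signature '", names(sigs)[j], "' has no genes in the matrix")
    if (length(genes) < length(sigs[[j]]))
      warning(length(sigs[[j]]) - length(genes), " gene(s) of signature '",
              names(sigs)[j], "' absent; dropped")
    ctrl <- unlist(lapply(genes, function(g) {
      pool <- which(bin == bin[match(g, rownames(ln))])
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
    out[, j] <- colMeans(ln[genes, , drop = FALSE]) -
      colMeans(ln[ctrl, , drop = FALSE])
  }
  new("ScoreMatrix", scores = out, method = "module", normalization = "none")
}

#' AUC recovery-curve score
#'
#' Per cell: the area under the recovery curve of signature genes within
#' the top `ceiling(top_frac * n_genes)` expression-ranked genes,
#' normalized by the maximal possible area (all signature genes at the very
#' top). Rank ties are broken by a gene order shuffled once with the given
#' seed, so scores are reproducible.
#'
#' @param expr a [LabeledExpression-class].
#' @param sigs named list of gene vectors.
#' @param top_frac fraction of the ranking considered (in (0, 1]).
#' @param seed seed for the tie-breaking shuffle.
#' @return A [ScoreMatrix-class] with values in \[0, 1\], cells in rows.
#' @export
aucSetScore <- function(expr, sigs, top_frac = 0.05, seed = 1) {
  stopifnot(is(expr, "LabeledExpression"))
  sigs <- .asSignatureList(sigs)
  if (!is.numeric(top_frac) || top_frac <= 0 || top_frac > 1)
    stop("'top_frac' must be in (0, 1]")
  X <- .asDense(assay(expr, "counts"))
  G <- nrow(X)
  maxRank <- ceiling(top_frac * G)
  ## tie-break order attaches to gene NAMES (sorted, then shuffled once),
  ## so scores do not depend on the row order of the input matrix
  set.seed(seed)
  shuffle <- integer(G)
  shuffle[order(rownames(X))] <- sample(G)
  sigIdx <- lapply(names(sigs), function(nm) {
    idx <- match(intersect(sigs[[nm]], rownames(X)), rownames(X))
    if (!length(idx)) stop("signature '", nm, "' has no genes in the matrix")
    idx
  })
  maxAuc <- vapply(sigIdx, function(idx) {
    k <- length(idx)
    if (k >= maxRank) maxRank * (maxRank + 1) / 2
    else k * (k + 1) / 2 + (maxRank - k) * k
  }, numeric(1))
  out <- matrix(0, ncol(X), length(sigs),
                dimnames = list(colnames(X), names(sigs)))
  for (cell in seq_len(ncol(X))) {
    ord <- order(-X[, cell], shuffle)
    rk <- integer(G)
    rk[ord] <- seq_len(G)
    for (j in seq_along(sigIdx)) {
      r <- rk[sigIdx[[j]]]
      r <- r[r <= maxRank]
      out[cell, j] <- sum(maxRank - r + 1) / maxAuc[j]
    }
  }
  new("ScoreMatrix", scores = out, method = "auc", normalization = "none")
}

#' Single-sample GSEA scores
#'
#' Rank-based running-sum enrichment per sample and signature: genes are
#' ranked within each sample (average ties), walked in decreasing rank
#' order, and the score is the sum over all positions of the difference
#' between the weighted in-set ECDF (in-set ranks weighted by
#' `rank^alpha`) and the unweighted out-of-set ECDF. With
#' `normalize = TRUE`, each signature's scores are divided by their
#' max - min across samples. Being rank-based, scores are invariant to any
#' per-sample strictly increasing transform of the expression values.
#'
#' @param expr a [LabeledExpression-class] (`unit = "sample"`, genes in
#'   rows) or any expression matrix-like object.
#' @param sigs named list of gene vectors; signatures with fewer than 2
#'   genes in the matrix are skipped with a warning.
#' @param config an [ssgseaConfig()].
#' @return A [ScoreMatrix-class], samples in rows.
#' @export
ssgseaScore <- function(expr, sigs, config = ssgseaConfig()) {
  stopifnot(inherits(config, "ssgsea_config"))
  X <- if (is(expr, "LabeledExpression")) .asDense(assay(expr, "counts"))
       else .asDense(expr)
  sigs <- .asSignatureList(sigs)
  keep <- vapply(sigs, function(g) length(intersect(g, rownames(X))) >= 2,
                 logical(1))
  if (any(!keep))
    warning("skipping signature(s) with < 2 genes present: ",
            paste(names(sigs)[!keep], collapse = ", "))
  sigs <- sigs[keep]
  if (!length(sigs)) stop("no scorable signatures")
  G <- nrow(X)
  out <- matrix(0, ncol(X), length(sigs),
                dimnames = list(colnames(X), names(sigs)))
  inSet <- lapply(sigs, function(g) rownames(X) %in% g)
  for (s in seq_len(ncol(X))) {
    r <- rank(X[, s])                 # average ties
    ord <- order(-r, rownames(X))     # walk order: ties by gene name
    ra <- r[ord]^config$alpha
    for (j in seq_along(sigs)) {
      ins <- inSet[[j]][ord]
      stepIn <- cumsum(ra * ins) / sum(ra[ins])
      stepOut <- cumsum(!ins) / (G - sum(ins))
      out[s, j] <- sum(stepIn - stepOut)
    }
  }
  if (config$normalize) {
    rng <- apply(out, 2, function(x) diff(range(x)))
    rng[rng == 0] <- 1
    out <- sweep(out, 2, rng, "/")
  }
  new("ScoreMatrix", scores = out, method = "ssgsea",
      normalization = if (config$normalize) "range" else "none")
}
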