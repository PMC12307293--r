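## Quality-control filters and marker-signature derivation.
## Boundary semantics are deliberate and literal: a cell with library size
## exactly at the UMI threshold, or mitochondrial fraction exactly at the
## cutoff, is EXCLUDED; a gene detected in exactly `min_cells_per_gene`
## cells is KEPT.

#' Filter cells by library size and mitochondrial fraction
#'
#' Retains exactly the cells with library size strictly greater than
#' `min_umi_exclusive` UMIs and mitochondrial read fraction strictly below
#' `max_mito_frac_exclusive`. A QC report (counts removed per criterion) is
#' stored in `metadata(result)$qc_report`.
#'
#' @param expr a [LabeledExpression-class] with integer counts.
#' @param qc a [qcThresholds()].
#' @return The filtered [LabeledExpression-class].
#' @examples
#' m <- matrix(c(1500, 2500, 3000), 1, 3,
#'             dimnames = list("G1", paste0("c", 1:3)))
#' le <- LabeledExpression(m, labels = rep("A", 3))
#' ncol(filterCells(le, qcThresholds(max_mito_frac_exclusive = 1)))
#' @export
filterCells <- function(expr, qc = qcThresholds()) {
  stopifnot(is(expr, "LabeledExpression"), inherits(qc, "qc_thresholds"))
  counts <- assay(expr, "counts")
  lib <- Matrix::colSums(counts)
  keepLib <- lib > qc$min_umi_exclusive
  mitoGenes <- startsWith(rownames(counts), qc$mito_prefix)
  if (!any(mitoGenes) && qc$max_mito_frac_exclusive < 1) {
    warning("no genes match mitochondrial prefix '", qc$mito_prefix,
            "'; mitochondrial criterion skipped")
    keepMito <- rep(TRUE, ncol(counts))
  } else {
    frac <- if (any(mitoGenes))
      Matrix::colSums(counts[mitoGenes, , drop = FALSE]) / pmax(lib, 1)
    else rep(0, ncol(counts))
    keepMito <- frac < qc$max_mito_frac_exclusive
  }
  keep <- keepLib & keepMito
  out <- expr[, keep]
  metadata(out)$qc_report <- list(
    n_input = ncol(counts), n_retained = sum(keep),
    n_removed_library = sum(!keepLib), n_removed_mito = sum(!keepMito),
    thresholds = qc)
  out
}

#' Filter (or flag) lowly detected genes
#'
#' Genes with nonzero counts in fewer than `min_cells_per_gene` cells are
#' removed (`mode = "remove"`) or only flagged in
#' `rowData(result)$detected` (`mode = "flag"`), mirroring the "marked as
#' undetected" reading.
#'
#' @param expr a [LabeledExpression-class].
#' @param qc a [qcThresholds()].
#' @param mode `"remove"` (default) or `"flag"`.
#' @return The filtered (or flagged) [LabeledExpression-class].
#' @export
filterGenes <- function(expr, qc = qcThresholds(), mode = c("remove", "flag")) {
  stopifnot(is(expr, "LabeledExpression"), inherits(qc, "qc_thresholds"))
  mode <- match.arg(mode)
  counts <- assay(expr, "counts")
  nCells <- Matrix::rowSums(counts > 0)
  keep <- nCells >= qc$min_cells_per_gene
  if (mode == "flag") {
    rowData(expr)$detected <- keep
    return(expr)
  }
  if (!any(keep)) stop("no genes survive the detection filter")
  expr[keep, ]
}

#' Filter spatial spots and genes
#'
#' Order of operations is fixed: spots with fewer than
#' `min_genes_per_spot` detected genes are removed first, then genes with a
#' total count below `min_counts_per_gene_spatial` or detected in fewer
#' than `min_spots_per_gene` of the surviving spots are removed.
#'
#' @param expr a [LabeledExpression-class] (`unit = "spot"`).
#' @param qc a [qcThresholds()].
#' @return The filtered [LabeledExpression-class].
#' @export
filterSpots <- function(expr, qc = qcThresholds()) {
  stopifnot(is(expr, "LabeledExpression"), inherits(qc, "qc_thresholds"))
  counts <- assay(expr, "counts")
  keepSpot <- Matrix::colSums(counts > 0) >= qc$min_genes_per_spot
  expr <- expr[, keepSpot]
  counts <- assay(expr, "counts")
  keepGene <- Matrix::rowSums(counts) >= qc$min_counts_per_gene_spatial &
    Matrix::rowSums(counts > 0) >= qc$min_spots_per_gene
  if (!any(keepGene)) stop("no genes survive the spatial filters")
  out <- expr[keepGene, ]
  metadata(out)$qc_report <- list(n_spots_removed = sum(!keepSpot),
                                  n_genes_removed = sum(!keepGene),
                                  thresholds = qc)
  out
}

## vectorized one-vs-rest Wilcoxon rank-sum (normal approximation with tie
## correction and continuity correction), one gene per row
#' @noRd
.rankSumTest <- function(ranks, tieTerm, inGroup) {
  N <- ncol(ranks)
  n1 <- sum(inGroup)
  n2 <- N - n1
  U <- rowSums(ranks[, inGroup, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(pmax(sigma2, 0))
  p <- 2 * pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  p
}

#' Rank per-type marker genes (top-30 rule)
#'
#' For each cell type, every gene is tested one-vs-rest with a two-sided
#' Wilcoxon rank-sum test on log-normalized expression (counts per 10k,
#' log1p); p-values are Benjamini-Hochberg adjusted per type. Genes passing
#' both the adjusted-p and average log2 fold-change criteria with a positive
#' fold change are ordered by fold change (ties: adjusted p, then gene
#' name) and truncated to `top_n`.
#'
#' The average log fold change is `log2(mean(expm1(ln_in)) + 1) -
#' log2(mean(expm1(ln_out)) + 1)` with `ln` the log-normalized values.
#'
#' @param expr a [LabeledExpression-class] with at least two cell types.
#' @param criteria a [markerCriteria()].
#' @return A named list of marker gene vectors (one per cell type), class
#'   `signature_set`, with the criteria and the full statistics table
#'   attached as attributes `criteria` and `stats`.
#' @export
rankMarkers <- function(expr, criteria = markerCriteria()) {
  stopifnot(is(expr, "LabeledExpression"), inherits(criteria, "marker_criteria"))
  labels <- cellLabels(expr)
  sizes <- table(labels)
  usable <- names(sizes)[sizes >= 3]
  if (length(usable) < 2)
    stop("need at least two cell types with >= 3 cells")
  if (length(usable) < length(sizes))
    warning("skipping cell type(s) with < 3 cells: ",
            paste(setdiff(names(sizes), usable), collapse = ", "))
  ln <- .asDense(.cp10kLog(assay(expr, "counts")))
  ranks <- t(apply(ln, 1, rank))
  tieTerm <- apply(ln, 1, function(x) {
    tt <- table(x)
    sum(tt^3 - tt)
  })
  expVals <- expm1(ln)
  sigs <- list()
  statsAll <- list()
  for (ct in usable) {
    inG <- labels == ct
    p <- .rankSumTest(ranks, tieTerm, inG)
    lfc <- log2(rowMeans(expVals[, inG, drop = FALSE]) + 1) -
      log2(rowMeans(expVals[, !inG, drop = FALSE]) + 1)
    padj <- p.adjust(p, method = "BH")
    tab <- data.frame(gene = rownames(ln), cell_type = ct, avg_log2FC = lfc,
                      p_val = p, p_adj = padj, stringsAsFactors = FALSE,
                      row.names = NULL)
    pass <- tab$p_adj <= criteria$max_adj_p &
      tab$avg_log2FC >= criteria$min_avg_logfc & tab$avg_log2FC > 0
    sel <- tab[pass, , drop = FALSE]
    sel <- sel[order(-sel$avg_log2FC, sel$p_adj, sel$gene), , drop = FALSE]
    sigs[[ct]] <- head(sel$gene, criteria$top_n)
    statsAll[[ct]] <- tab
  }
  structure(sigs, criteria = criteria, stats = do.call(rbind, statsAll),
            class = "signature_set")
}
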