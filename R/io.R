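## Plain-text interchange: Matrix-Market expression bundles, edge-list and
## score TSVs, GMT gene sets.

#' Write a labeled expression bundle
#'
#' Writes `matrix.mtx` (Matrix-Market triplet), `genes.tsv`,
#' `barcodes.tsv` and `labels.tsv` into a directory.
#'
#' @param expr a [LabeledExpression-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeExpressionDir <- function(expr, dir) {
  stopifnot(is(expr, "LabeledExpression"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- assay(expr, "counts")
  if (!inherits(m, "sparseMatrix"))
    m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(expr), file.path(dir, "genes.tsv"))
  writeLines(colnames(expr), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(barcode = colnames(expr), label = cellLabels(expr)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a labeled expression bundle written by [writeExpressionDir()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `labels.tsv`.
#' @param unit column unit tag (`"cell"`, `"spot"` or `"sample"`).
#' @return A [LabeledExpression-class].
#' @export
readExpressionDir <- function(dir, unit = "cell") {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  LabeledExpression(m, labels = lab$label[match(colnames(m), lab$barcode)],
                    unit = unit)
}

#' Write / read a network edge list
#'
#' Tab-separated `source`, `target`, `weight`; isolated nodes are kept in a
#' header comment so the round trip preserves the node universe.
#'
#' @param net a [CommNetwork-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "CommNetwork"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes: ", paste(networkNodes(net), collapse = ",")), con)
  e <- networkEdges(net)
  writeLines("source\ttarget\tweight", con)
  if (nrow(e))
    writeLines(sprintf("%s\t%s\t%.17g", e$from, e$to, e$weight), con)
  invisible(path)
}

#' @rdname writeEdgeList
#' @param path TSV path to read.
#' @export
readEdgeList <- function(path) {
  first <- readLines(path, n = 1)
  nodes <- NULL
  if (startsWith(first, "# nodes:"))
    nodes <- strsplit(trimws(sub("# nodes:", "", first)), ",")[[1]]
  e <- utils::read.delim(path, comment.char = "#")
  colnames(e) <- c("from", "to", "weight")
  CommNetwork(e, nodes = nodes)
}

#' Write gene signatures in GMT format
#'
#' One tab-separated line per set: name, description, genes.
#'
#' @param sigs named list of gene vectors (or a `signature_set`).
#' @param path output path.
#' @param description per-set description (recycled).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sigs, path, description = "commotif") {
  sigs <- .asSignatureList(sigs)
  description <- rep_len(description, length(sigs))
  lines <- vapply(seq_along(sigs), function(i)
    paste(c(names(sigs)[i], description[i], sigs[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
  fields <- strsplit(readLines(path), "\t")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  sets
}

#' Write a score matrix or census / null-stats table as TSV
#'
#' @param x a [ScoreMatrix-class], [MotifCensus-class] or
#'   [NullEnsembleStats-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeResultTsv <- function(x, path) {
  tab <- if (is(x, "ScoreMatrix")) {
    data.frame(sample = rownames(scoreValues(x)), scoreValues(x),
               check.names = FALSE)
  } else if (is(x, "MotifCensus")) {
    censusTable(x)
  } else if (is(x, "NullEnsembleStats")) {
    nullStats(x)
  } else if (is.data.frame(x)) {
    x
  } else stop("unsupported object")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
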