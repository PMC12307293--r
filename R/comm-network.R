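## Ligand-receptor communication strengths and their aggregation into a
## weighted directed cell-type network.
##
## The per-pair score is a documented simplified surrogate for full
## communication-probability machinery: a saturating mass-action (Hill)
## score on trimmed-mean log-normalized expression,
##   strength(s -> r) = L*R / (hill_k + L*R),
## with L the trimmed mean ligand expression in the sender (geometric mean
## over subunits) and R likewise for the receptor in the receiver. It is
## bounded in [0, 1), monotone in both L and R, and zero whenever either
## side is silent -- all that downstream motif machinery requires.

#' @noRd
.splitSubunits <- function(x) strsplit(as.character(x), "+", fixed = TRUE)

## trimmed-mean expression of selected genes per cell type; absent genes 0
#' @noRd
.typeMeans <- function(ln, labels, genes, types, trim) {
  tm <- matrix(0, length(genes), length(types),
               dimnames = list(genes, types))
  present <- genes %in% rownames(ln)
  for (ct in types) {
    sub <- ln[genes[present], labels == ct, drop = FALSE]
    tm[present, ct] <- apply(.asDense(sub), 1, mean, trim = trim)
  }
  tm
}

#' Ligand-receptor communication strengths between cell types
#'
#' Computes, for every ligand-receptor pair and every ordered (sender,
#' receiver) combination of sufficiently large cell types, the saturating
#' mass-action strength described above. Cell types with fewer than
#' `min_cells` cells contribute no interactions (neither as sender nor as
#' receiver). Pair genes absent from the matrix score 0 (noted once).
#'
#' @param expr a [LabeledExpression-class].
#' @param pairs data.frame with columns `ligand`, `receptor` and optional
#'   `pathway`; multi-subunit genes joined with `"+"`.
#' @param config a [commConfig()].
#' @return data.frame with one row per (pair, sender, receiver):
#'   columns `ligand`, `receptor`, `pathway`, `sender`, `receiver`, `L`,
#'   `R`, `strength`. The full cell-type universe (including excluded
#'   types) is attached as attribute `all_types`.
#' @export
commStrength <- function(expr, pairs, config = commConfig()) {
  stopifnot(is(expr, "LabeledExpression"), inherits(config, "comm_config"))
  pairs <- as.data.frame(pairs)
  if (!all(c("ligand", "receptor") %in% colnames(pairs)))
    stop("'pairs' needs columns 'ligand' and 'receptor'")
  if (is.null(pairs$pathway)) pairs$pathway <- pairs$ligand
  labels <- cellLabels(expr)
  if (anyNA(labels)) stop("all cells must carry a label")
  allTypes <- sort(unique(labels))
  sizes <- table(labels)
  types <- names(sizes)[sizes >= config$min_cells]
  ln <- .cp10kLog(assay(expr, "counts"))
  ligList <- .splitSubunits(pairs$ligand)
  recList <- .splitSubunits(pairs$receptor)
  genes <- unique(unlist(c(ligList, recList)))
  missing <- setdiff(genes, rownames(ln))
  if (length(missing))
    message(length(missing), " pair gene(s) absent from the matrix; ",
            "their interactions score 0")
  tm <- .typeMeans(ln, labels, genes, types, config$trim_frac)
  geomMean <- function(gs, ct) exp(mean(log(pmax(tm[gs, ct], 0) + 1e-300))) *
    (all(tm[gs, ct] > 0))
  grid <- expand.grid(pair = seq_len(nrow(pairs)), sender = types,
                      receiver = types, stringsAsFactors = FALSE)
  L <- mapply(function(p, s) geomMean(ligList[[p]], s), grid$pair, grid$sender)
  R <- mapply(function(p, r) geomMean(recList[[p]], r), grid$pair, grid$receiver)
  LR <- L * R
  out <- data.frame(ligand = pairs$ligand[grid$pair],
                    receptor = pairs$receptor[grid$pair],
                    pathway = pairs$pathway[grid$pair],
                    sender = grid$sender, receiver = grid$receiver,
                    L = L, R = R, strength = LR / (config$hill_k + LR),
                    stringsAsFactors = FALSE)
  attr(out, "all_types") <- allTypes
  attr(out, "config") <- config
  out
}

#' Aggregate pair strengths into a communication network
#'
#' Edge weight s -> r is the sum of strengths over all ligand-receptor
#' pairs; the per-pathway breakdown is retained. Cell types excluded
#' upstream (below `min_cells`) appear as isolated nodes.
#'
#' @param strengths output of [commStrength()].
#' @param nodes optional full node universe; defaults to the `all_types`
#'   attribute of `strengths`.
#' @return A [CommNetwork-class].
#' @export
aggregateNetwork <- function(strengths, nodes = NULL) {
  if (!nrow(strengths)) stop("empty strength table")
  if (is.null(nodes)) nodes <- attr(strengths, "all_types")
  if (is.null(nodes)) nodes <- sort(unique(c(strengths$sender, strengths$receiver)))
  agg <- aggregate(strength ~ sender + receiver, data = strengths, FUN = sum)
  agg <- agg[agg$strength > 0, , drop = FALSE]
  pw <- aggregate(strength ~ sender + receiver + pathway, data = strengths,
                  FUN = sum)
  pw <- pw[pw$strength > 0, , drop = FALSE]
  CommNetwork(
    data.frame(from = agg$sender, to = agg$receiver, weight = agg$strength,
               stringsAsFactors = FALSE),
    nodes = nodes,
    pathways = data.frame(from = pw$sender, to = pw$receiver,
                          pathway = pw$pathway, weight = pw$strength,
                          stringsAsFactors = FALSE),
    metadata = list(config = attr(strengths, "config")))
}

#' Compare communication strengths between two response groups
#'
#' Computes per-sample strength tables for each group (patients as
#' replicates), takes the difference of group means for every
#' (pair, sender, receiver) combination, and attaches a two-sided
#' label-permutation p-value with add-one smoothing,
#' `p = (1 + #\{|diff_perm| >= |diff_obs|\}) / (1 + n_perm)`.
#'
#' @param expr_groups named list of exactly two groups, each a list of
#'   [LabeledExpression-class] sample objects (>= 2 samples per group).
#'   The difference reported is `mean(first group) - mean(second group)`.
#' @param pairs ligand-receptor pair table (see [commStrength()]).
#' @param config a [commConfig()].
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return data.frame keyed by (ligand, receptor, sender, receiver) with
#'   group means, `diff` and permutation `p`.
#' @export
compareGroups <- function(expr_groups, pairs, config = commConfig(),
                          n_perm = 999, seed = 1) {
  if (length(expr_groups) != 2 || is.null(names(expr_groups)))
    stop("'expr_groups' must be a named list of two groups")
  nPer <- lengths(expr_groups)
  if (any(nPer < 2)) stop("each group needs at least 2 samples")
  .assertScalar(n_perm, "n_perm", min = 1, integer = TRUE)
  samples <- c(expr_groups[[1]], expr_groups[[2]])
  groupOf <- rep(c(1L, 2L), nPer)
  tabs <- lapply(samples, function(s) commStrength(s, pairs, config))
  keys <- unique(do.call(rbind, lapply(tabs, function(t)
    t[, c("ligand", "receptor", "sender", "receiver")])))
  keyStr <- function(t) paste(t$ligand, t$receptor, t$sender, t$receiver,
                              sep = "\r")
  kAll <- keyStr(keys)
  M <- sapply(tabs, function(t) {
    v <- setNames(t$strength, keyStr(t))
    out <- v[kAll]
    out[is.na(out)] <- 0  # sample lacked that cell type: no interaction
    out
  })
  g1 <- groupOf == 1L
  diffObs <- rowMeans(M[, g1, drop = FALSE]) - rowMeans(M[, !g1, drop = FALSE])
  set.seed(seed)
  exceed <- numeric(length(diffObs))
  for (b in seq_len(n_perm)) {
    perm <- sample(groupOf)
    d <- rowMeans(M[, perm == 1L, drop = FALSE]) -
      rowMeans(M[, perm == 2L, drop = FALSE])
    exceed <- exceed + (abs(d) >= abs(diffObs) - 1e-12)
  }
  data.frame(keys,
             mean_g1 = rowMeans(M[, g1, drop = FALSE]),
             mean_g2 = rowMeans(M[, !g1, drop = FALSE]),
             diff = diffObs,
             p = (1 + exceed) / (1 + n_perm),
             row.names = NULL, stringsAsFactors = FALSE)
}
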