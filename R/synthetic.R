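## Synthetic-data generators: every input the pipeline consumes can be
## produced here, with planted structure whose recovery the tests check.

#' Configuration for the single-cell count simulator
#'
#' Cells are drawn per cell type from a negative-binomial model with a
#' shared dispersion and log-normal gene-level baseline means. Each type
#' gets a block of planted marker genes elevated by `marker_log2fc`;
#' ligand-receptor activity is planted by elevating a ligand gene in a
#' sender type and a receptor gene in a receiver type by a fold-change.
#' A fraction of genes is named with the mitochondrial prefix so QC filters
#' are exercisable.
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type cells simulated per type.
#' @param n_genes total genes.
#' @param n_markers_per_type planted marker genes per type.
#' @param marker_log2fc log2 fold elevation of a marker in its own type.
#' @param baseline_mean baseline negative-binomial mean scale.
#' @param nb_dispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2).
#' @param lr_plants list of planted interactions, each
#'   `list(ligand =, receptor =, sender =, receiver =, fc =)` with gene
#'   indices, cell-type indices and fold-change >= 1.
#' @param mito_frac fraction of genes flagged with `mito_prefix`.
#' @param mito_prefix gene-name prefix for mitochondrial genes.
#' @param seed RNG seed.
#' @return A `sc_sim_config` list.
#' @export
scSimConfig <- function(n_cell_types = 4, cells_per_type = 100, n_genes = 500,
                        n_markers_per_type = 10, marker_log2fc = 2,
                        baseline_mean = 0.5, nb_dispersion = 0.5,
                        lr_plants = list(), mito_frac = 0.02,
                        mito_prefix = "MT-", seed = 1) {
  .assertScalar(n_cell_types, "n_cell_types", min = 1, integer = TRUE)
  .assertScalar(cells_per_type, "cells_per_type", min = 1, integer = TRUE)
  .assertScalar(n_genes, "n_genes", min = 1, integer = TRUE)
  .assertScalar(n_markers_per_type, "n_markers_per_type", min = 0, integer = TRUE)
  .assertScalar(marker_log2fc, "marker_log2fc", min = 0)
  .assertScalar(baseline_mean, "baseline_mean", min = 1e-12)
  .assertScalar(nb_dispersion, "nb_dispersion", min = 1e-12)
  .assertScalar(mito_frac, "mito_frac", 0, 0.5)
  .assertScalar(seed, "seed", integer = TRUE)
  n_mito <- round(mito_frac * n_genes)
  if (n_cell_types * n_markers_per_type > n_genes - n_mito)
    stop("not enough non-mitochondrial genes for the requested markers")
  for (p in lr_plants) {
    if (!all(c("ligand", "receptor", "sender", "receiver", "fc") %in% names(p)))
      stop("each lr_plant needs ligand, receptor, sender, receiver, fc")
    if (p$ligand == p$receptor)
      stop("planted ligand and receptor must be distinct gene indices")
    if (p$ligand > n_genes || p$receptor > n_genes || p$ligand < 1 || p$receptor < 1)
      stop("planted gene index out of range")
    if (p$sender > n_cell_types || p$receiver > n_cell_types)
      stop("planted cell-type index out of range")
    if (p$fc < 1) stop("planted fold-change must be >= 1")
  }
  structure(as.list(environment())[c("n_cell_types", "cells_per_type",
    "n_genes", "n_markers_per_type", "marker_log2fc", "baseline_mean",
    "nb_dispersion", "lr_plants", "mito_frac", "mito_prefix", "seed")],
    class = "sc_sim_config")
}

#' Simulate labeled single-cell counts with planted structure
#'
#' @param config an [scSimConfig()].
#' @return A [LabeledExpression-class] (`unit = "cell"`). `rowData` flags
#'   mitochondrial genes and records which type (if any) each gene marks;
#'   `metadata(x)$truth` holds the planted markers and interactions.
#' @examples
#' sce <- simulateScCounts(scSimConfig(n_cell_types = 2, cells_per_type = 20,
#'                                     n_genes = 100, seed = 7))
#' table(cellLabels(sce))
#' @export
simulateScCounts <- function(config = scSimConfig()) {
  stopifnot(inherits(config, "sc_sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  Tt <- config$n_cell_types
  n_mito <- round(config$mito_frac * G)
  geneNames <- sprintf("G%05d", seq_len(G))
  isMito <- rep(FALSE, G)
  if (n_mito > 0) {
    ## mito genes are the last block so marker blocks never overlap them
    mitoIdx <- (G - n_mito + 1):G
    isMito[mitoIdx] <- TRUE
    geneNames[mitoIdx] <- paste0(config$mito_prefix, sprintf("%03d", seq_len(n_mito)))
  }
  typeNames <- sprintf("CT%02d", seq_len(Tt))
  geneMu <- config$baseline_mean * exp(rnorm(G, 0, 0.5))

  markerOf <- rep(NA_integer_, G)
  if (config$n_markers_per_type > 0)
    for (t in seq_len(Tt)) {
      idx <- ((t - 1) * config$n_markers_per_type + 1):(t * config$n_markers_per_type)
      markerOf[idx] <- t
    }

  ## per-type mean matrix: baseline x marker elevation x planted LR activity
  mu <- matrix(geneMu, G, Tt)
  for (t in seq_len(Tt))
    mu[which(markerOf == t), t] <- mu[which(markerOf == t), t] * 2^config$marker_log2fc
  for (p in config$lr_plants) {
    mu[p$ligand, p$sender] <- mu[p$ligand, p$sender] * p$fc
    mu[p$receptor, p$receiver] <- mu[p$receptor, p$receiver] * p$fc
  }

  nc <- config$cells_per_type
  counts <- matrix(0L, G, Tt * nc)
  for (t in seq_len(Tt)) {
    block <- rnbinom(G * nc, mu = rep(mu[, t], nc), size = 1 / config$nb_dispersion)
    counts[, ((t - 1) * nc + 1):(t * nc)] <- as.integer(block)
  }
  rownames(counts) <- geneNames
  colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  labels <- rep(typeNames, each = nc)
  le <- LabeledExpression(
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    labels = labels, unit = "cell",
    rowData = DataFrame(is_mito = isMito,
                        marker_of = ifelse(is.na(markerOf), NA_character_,
                                           typeNames[markerOf])),
    metadata = list(truth = list(
      markers = split(geneNames[!is.na(markerOf)], typeNames[markerOf[!is.na(markerOf)]]),
      lr_plants = lapply(config$lr_plants, function(p)
        list(ligand = geneNames[p$ligand], receptor = geneNames[p$receptor],
             sender = typeNames[p$sender], receiver = typeNames[p$receiver],
             fc = p$fc)),
      config = config)))
  le
}

#' Specification for the planted-motif digraph simulator
#'
#' @param out_degree_seq,in_degree_seq integer degree sequences (equal
#'   sums, realizable as a simple digraph without self-loops).
#' @param planted_motifs list of `list(class =, count =, boost =)`: a motif
#'   alias (see [motifAdjacency()]) or adjacency matrix, the number of
#'   instances to plant, and the multiplicative weight boost (> 0) applied
#'   to the instance edges.
#' @param weight_meanlog,weight_sdlog log-normal parameters of the
#'   background edge-weight distribution.
#' @param seed RNG seed.
#' @return A `graph_sim_spec` list.
#' @export
graphSimSpec <- function(out_degree_seq, in_degree_seq,
                         planted_motifs = list(),
                         weight_meanlog = -1, weight_sdlog = 0.5, seed = 1) {
  out_degree_seq <- as.integer(out_degree_seq)
  in_degree_seq <- as.integer(in_degree_seq)
  if (length(out_degree_seq) != length(in_degree_seq))
    stop("degree sequences must have equal length")
  if (sum(out_degree_seq) != sum(in_degree_seq))
    stop("degree sequences must have equal sums")
  if (any(out_degree_seq < 0) || any(in_degree_seq < 0))
    stop("degrees must be non-negative")
  n <- length(out_degree_seq)
  if (any(out_degree_seq > n - 1) || any(in_degree_seq > n - 1))
    stop("degree sequences not graphical for a simple digraph without self-loops")
  for (p in planted_motifs) {
    if (!all(c("class", "count", "boost") %in% names(p)))
      stop("each planted motif needs class, count, boost")
    if (p$count < 0 || p$boost <= 0) stop("planted count >= 0 and boost > 0 required")
  }
  .assertScalar(seed, "seed", integer = TRUE)
  structure(list(n_nodes = n, out_degree_seq = out_degree_seq,
                 in_degree_seq = in_degree_seq, planted_motifs = planted_motifs,
                 weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
                 seed = as.integer(seed)),
            class = "graph_sim_spec")
}

## permutation that is safe for length-1 vectors (sample() would misread them)
#' @noRd
.resample <- function(x) x[sample.int(length(x))]

## create arc u->v in logical adjacency A by a degree-preserving double swap;
## `frozen` is a set of ordered node pairs (linear indices (col-1)*n + row)
## that must not change state -- neither lose nor gain an arc. Returns the
## updated matrix or NULL if no legal swap exists.
#' @noRd
.swapInEdge <- function(A, u, v, frozen) {
  n <- nrow(A)
  xs <- which(A[u, ] & seq_len(n) != v)           # u -> x candidates
  xs <- xs[!((xs - 1) * n + u) %in% frozen]
  ys <- which(A[, v] & seq_len(n) != u)           # y -> v candidates
  ys <- ys[!((v - 1) * n + ys) %in% frozen]
  for (x in .resample(xs)) {
    for (y in .resample(ys)) {
      if (y != x && !A[y, x] && y != u && x != v &&
          !((x - 1) * n + y) %in% frozen) {       # added arc y -> x
        A[u, x] <- FALSE; A[y, v] <- FALSE
        A[u, v] <- TRUE;  A[y, x] <- TRUE
        return(A)
      }
    }
  }
  NULL
}

## remove arc p->q by a degree-preserving double swap avoiding `frozen`
#' @noRd
.swapOutEdge <- function(A, p, q, frozen) {
  n <- nrow(A)
  cand <- which(A & !(diag(n) > 0), arr.ind = TRUE)
  cand <- cand[cand[, 1] != p & cand[, 2] != q, , drop = FALSE]
  if (nrow(cand) > 1) cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; s <- cand[i, 2]
    if (((s - 1) * n + r) %in% frozen) next        # removed arc r -> s
    if (s == p || r == q) next                     # would self-loop
    if (A[p, s] || A[r, q]) next                   # would duplicate
    if (((s - 1) * n + p) %in% frozen) next        # added arc p -> s
    if (((q - 1) * n + r) %in% frozen) next        # added arc r -> q
    A[p, q] <- FALSE; A[r, s] <- FALSE
    A[p, s] <- TRUE;  A[r, q] <- TRUE
    return(A)
  }
  NULL
}

#' Simulate a weighted digraph with exact degrees and planted motifs
#'
#' Realizes the requested in/out degree sequences exactly as a simple
#' digraph (configuration-model realization with rejection of self-loops
#' and multi-edges), then plants the requested motif instances by targeted
#' degree-preserving double-edge swaps that force the induced subgraph on a
#' sampled node set to match the motif class. Background edge weights are
#' i.i.d. log-normal; edges of planted instances are multiplied by the
#' motif's weight boost.
#'
#' @param spec a [graphSimSpec()].
#' @param max_tries attempts at realizing all planted motifs before giving
#'   up with an error.
#' @return A [CommNetwork-class]; `metadata(net)$planted` records the node
#'   sets, class ids and boosts of the planted instances.
#' @examples
#' spec <- graphSimSpec(rep(2, 10), rep(2, 10),
#'                      planted_motifs = list(list(class = "ffl", count = 2,
#'                                                 boost = 5)), seed = 3)
#' net <- simulateCommGraph(spec)
#' @export
simulateCommGraph <- function(spec, max_tries = 50) {
  stopifnot(inherits(spec, "graph_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  nodes <- sprintf("N%02d", seq_len(n))
  for (attempt in seq_len(max_tries)) {
    g <- tryCatch(
      igraph::sample_degseq(spec$out_degree_seq, spec$in_degree_seq,
                            method = "configuration.simple"),
      error = function(e) NULL)
    if (is.null(g)) next
    A <- matrix(FALSE, n, n)
    el <- igraph::as_edgelist(g, names = FALSE)
    A[el] <- TRUE
    planted <- list()
    frozen <- integer(0)   # ordered pairs inside planted instances, fixed state
    ok <- TRUE
    for (pm in spec$planted_motifs) {
      target <- if (is.character(pm$class)) motifAdjacency(pm$class) else as.matrix(pm$class)
      k <- nrow(target)
      cnt <- 0
      for (rep_i in seq_len(300L)) {
        if (cnt >= pm$count) break
        sel <- sample(n, k)
        selPairs <- expand.grid(a = sel, b = sel)
        selPairs <- selPairs[selPairs$a != selPairs$b, , drop = FALSE]
        selPairIdx <- (selPairs$b - 1) * n + selPairs$a
        ## node sets whose pairs overlap an earlier instance cannot be edited
        if (any(selPairIdx %in% frozen)) next
        Anew <- A
        good <- TRUE
        for (a in seq_len(k)) for (b in seq_len(k)) {
          if (a == b) next
          want <- target[a, b] != 0
          have <- Anew[sel[a], sel[b]]
          if (want && !have) {
            Anew2 <- .swapInEdge(Anew, sel[a], sel[b], frozen)
            if (is.null(Anew2)) { good <- FALSE; break }
            Anew <- Anew2
          } else if (!want && have) {
            Anew2 <- .swapOutEdge(Anew, sel[a], sel[b], frozen)
            if (is.null(Anew2)) { good <- FALSE; break }
            Anew <- Anew2
          }
        }
        if (!good) next
        ## a later swap may have disturbed an earlier pair of this instance
        ind <- Anew[sel, sel]; diag(ind) <- FALSE
        if (!all((ind != 0) == (target != 0))) next
        A <- Anew
        cnt <- cnt + 1
        instArcs <- which(target != 0, arr.ind = TRUE)
        arcIdx <- (sel[instArcs[, 2]] - 1) * n + sel[instArcs[, 1]]
        frozen <- c(frozen, selPairIdx)
        planted[[length(planted) + 1]] <-
          list(nodes = nodes[sel], class_id = canonicalClass(target)$id,
               class = if (is.character(pm$class)) pm$class else NA_character_,
               boost = pm$boost, arcs = arcIdx)
      }
      if (cnt < pm$count) { ok <- FALSE; break }
    }
    if (!ok) next
    ## degrees must be untouched by planting
    stopifnot(identical(as.integer(rowSums(A)), spec$out_degree_seq),
              identical(as.integer(colSums(A)), spec$in_degree_seq))
    idx <- which(A, arr.ind = TRUE)
    w <- rlnorm(nrow(idx), spec$weight_meanlog, spec$weight_sdlog)
    lin <- (idx[, 2] - 1) * n + idx[, 1]
    for (pl in planted) w[lin %in% pl$arcs] <- w[lin %in% pl$arcs] * pl$boost
    edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                        weight = w, stringsAsFactors = FALSE)
    return(CommNetwork(edges, nodes = nodes,
                       metadata = list(planted = planted, spec = spec)))
  }
  stop("could not realize the degree sequence with all planted motifs; ",
       "sequence may be unrealizable or too constrained")
}

#' Configuration for the bulk-mixture simulator
#'
#' Samples-by-genes expression where the genes of each signature are
#' shifted per subtype by `group_effect` on top of gene baselines and
#' Gaussian noise, emulating bulk cohorts with a planted subtype structure.
#'
#' @param n_samples number of bulk samples.
#' @param n_genes total genes.
#' @param signatures named list of gene-name vectors; default: 4 disjoint
#'   15-gene signatures.
#' @param group_assignments integer subtype (1..k_true) per sample; default
#'   balanced assignment over `k_true` groups.
#' @param k_true number of planted subtypes (>= 2).
#' @param group_effect k_true-by-signatures matrix of mean shifts; default
#'   `5 * noise_sd` for the signature matching each subtype, 0 elsewhere.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return A `bulk_sim_config` list.
#' @export
bulkSimConfig <- function(n_samples = 60, n_genes = 200, signatures = NULL,
                          group_assignments = NULL, k_true = 4,
                          group_effect = NULL, noise_sd = 1, seed = 1) {
  .assertScalar(n_samples, "n_samples", min = 2, integer = TRUE)
  .assertScalar(n_genes, "n_genes", min = 2, integer = TRUE)
  .assertScalar(k_true, "k_true", min = 2, integer = TRUE)
  .assertScalar(noise_sd, "noise_sd", min = 1e-12)
  .assertScalar(seed, "seed", integer = TRUE)
  geneNames <- sprintf("G%05d", seq_len(n_genes))
  if (is.null(signatures)) {
    if (n_genes < k_true * 15) stop("n_genes too small for default signatures")
    signatures <- lapply(seq_len(k_true), function(i)
      geneNames[((i - 1) * 15 + 1):(i * 15)])
    names(signatures) <- sprintf("Sig%d", seq_len(k_true))
  }
  bad <- setdiff(unlist(signatures), geneNames)
  if (length(bad))
    stop("signature genes outside the simulated gene universe: ",
         paste(head(bad, 3), collapse = ", "))
  if (is.null(group_assignments))
    group_assignments <- rep(seq_len(k_true), length.out = n_samples)
  group_assignments <- as.integer(group_assignments)
  if (length(group_assignments) != n_samples)
    stop("one subtype per sample required")
  if (!all(group_assignments %in% seq_len(k_true)))
    stop("group assignments must be in 1..k_true")
  if (is.null(group_effect)) {
    group_effect <- matrix(0, k_true, length(signatures),
                           dimnames = list(NULL, names(signatures)))
    for (i in seq_len(min(k_true, length(signatures))))
      group_effect[i, i] <- 5 * noise_sd
  }
  group_effect <- as.matrix(group_effect)
  if (nrow(group_effect) != k_true || ncol(group_effect) != length(signatures))
    stop("group_effect must be k_true x n_signatures")
  colnames(group_effect) <- names(signatures)
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 signatures = signatures, group_assignments = group_assignments,
                 k_true = k_true, group_effect = group_effect,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Simulate bulk expression with planted subtype structure
#'
#' @param config a [bulkSimConfig()].
#' @return A [LabeledExpression-class] (`unit = "sample"`, genes in rows,
#'   samples in columns) whose `label` column holds the true subtype
#'   (`"S1"`, `"S2"`, ...); `metadata(x)$truth` echoes the planted design.
#' @export
simulateBulkMixtures <- function(config = bulkSimConfig()) {
  stopifnot(inherits(config, "bulk_sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  geneNames <- sprintf("G%05d", seq_len(G))
  base <- rnorm(G, mean = 5, sd = 1.5)
  X <- matrix(rnorm(G * config$n_samples, 0, config$noise_sd),
              G, config$n_samples) + base
  for (j in seq_along(config$signatures)) {
    gi <- match(config$signatures[[j]], geneNames)
    for (s in seq_len(config$n_samples))
      X[gi, s] <- X[gi, s] + config$group_effect[config$group_assignments[s], j]
  }
  rownames(X) <- geneNames
  colnames(X) <- sprintf("sample%03d", seq_len(config$n_samples))
  LabeledExpression(X, labels = sprintf("S%d", config$group_assignments),
                    unit = "sample",
                    metadata = list(truth = list(
                      subtype = config$group_assignments,
                      signatures = config$signatures,
                      group_effect = config$group_effect,
                      config = config)))
}
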