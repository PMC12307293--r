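## End-to-end orchestration: synthetic (or user) inputs -> QC -> markers ->
## communication network -> hierarchy -> motif census + null -> bulk scores
## -> TME subtypes, with a JSON run manifest.

#' Pipeline configuration
#'
#' Bundles per-stage configurations and stage toggles. All stage seeds are
#' derived deterministically from the single global `seed`, so a run is a
#' pure function of its configuration. The default configuration runs the
#' whole chain on synthetic data.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param stages character vector of stages to run, a subset of
#'   `c("sc", "qc", "markers", "comm", "hierarchy", "motifs", "bulk",
#'   "scores", "tme")`. Dependencies must be satisfied: e.g. `"comm"`
#'   needs `"qc"` and `"markers"` outputs unless `sc_dir` points at data.
#' @param sc_config an [scSimConfig()] for the synthetic single-cell stage
#'   (its seed field is overridden by the derived stage seed).
#' @param sc_dir optional directory of an existing expression bundle
#'   (see [readExpressionDir()]) used instead of simulation.
#' @param qc a [qcThresholds()].
#' @param markers a [markerCriteria()].
#' @param comm a [commConfig()].
#' @param lr_pairs optional ligand-receptor pair data.frame; by default the
#'   planted pairs of the synthetic stage plus `n_background_pairs` random
#'   gene pairs.
#' @param n_background_pairs random background pairs added to the planted
#'   ones.
#' @param prune_min_weight edge-pruning threshold before hierarchy/motifs.
#' @param null a [nullConfig()] for motif significance.
#' @param motif_sizes motif sizes to census.
#' @param bulk_config a [bulkSimConfig()] for the synthetic bulk stage.
#' @param ssgsea an [ssgseaConfig()].
#' @param cluster a [clusterConfig()].
#' @param barrier_sigs,exhaustion_sigs signature names used for semantic
#'   subtype labels.
#' @return A `pipeline_config` list.
#' @export
pipelineConfig <- function(seed = 1,
                           stages = c("sc", "qc", "markers", "comm",
                                      "hierarchy", "motifs", "bulk",
                                      "scores", "tme"),
                           sc_config = scSimConfig(
                             n_cell_types = 6, cells_per_type = 150,
                             n_genes = 600, n_markers_per_type = 10,
                             marker_log2fc = 2, baseline_mean = 4,
                             nb_dispersion = 0.5,
                             lr_plants = list(
                               list(ligand = 400, receptor = 401, sender = 1,
                                    receiver = 2, fc = 8),
                               list(ligand = 402, receptor = 403, sender = 2,
                                    receiver = 3, fc = 8),
                               list(ligand = 404, receptor = 405, sender = 1,
                                    receiver = 4, fc = 6))),
                           sc_dir = NULL,
                           qc = qcThresholds(),
                           markers = markerCriteria(),
                           comm = commConfig(),
                           lr_pairs = NULL,
                           n_background_pairs = 10,
                           prune_min_weight = 1e-4,
                           null = nullConfig(),
                           motif_sizes = c(2, 3, 4),
                           bulk_config = bulkSimConfig(),
                           ssgsea = ssgseaConfig(),
                           cluster = clusterConfig(),
                           barrier_sigs = "Sig1",
                           exhaustion_sigs = "Sig2") {
  .assertScalar(seed, "seed", integer = TRUE)
  known <- c("sc", "qc", "markers", "comm", "hierarchy", "motifs", "bulk",
             "scores", "tme")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(as.list(environment())[c("seed", "stages", "sc_config", "sc_dir",
    "qc", "markers", "comm", "lr_pairs", "n_background_pairs",
    "prune_min_weight", "null", "motif_sizes", "bulk_config", "ssgsea",
    "cluster", "barrier_sigs", "exhaustion_sigs")],
    class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' The YAML may set `seed`, `stages` and, per stage, any argument of the
#' corresponding configuration constructor, e.g.
#'
#' ```yaml
#' seed: 7
#' stages: [sc, qc, markers, comm]
#' qc: {min_umi_exclusive: 1000}
#' null: {n_random: 5000}
#' sc: {n_cell_types: 5, cells_per_type: 200}
#' ```
#'
#' Unset fields keep the [pipelineConfig()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
pipelineConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  ctor <- list(sc = "sc_config", qc = "qc", markers = "markers",
               comm = "comm", null = "null", ssgsea = "ssgsea",
               cluster = "cluster", bulk = "bulk_config")
  fun <- list(sc = scSimConfig, qc = qcThresholds, markers = markerCriteria,
              comm = commConfig, null = nullConfig, ssgsea = ssgseaConfig,
              cluster = clusterConfig, bulk = bulkSimConfig)
  for (k in names(ctor)) {
    if (!is.null(y[[k]])) args[[ctor[[k]]]] <- do.call(fun[[k]], y[[k]])
  }
  for (k in c("sc_dir", "lr_pairs", "n_background_pairs", "prune_min_weight",
              "motif_sizes", "barrier_sigs", "exhaustion_sigs")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipelineConfig, args)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order, writes per-stage
#' outputs under `out_dir` and a `manifest.json` recording, per stage, its
#' status (`"ok"` / `"skipped"`), derived seed, key result sizes and output
#' files. Re-running with an identical configuration reproduces identical
#' outputs and manifest.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir output directory.
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on <- function(s) s %in% config$stages
  manifest <- list(global_seed = config$seed,
                   package_version = as.character(utils::packageVersion("commotif")),
                   stages = list())
  note <- function(stage, status, seed = NULL, ...) {
    manifest$stages[[stage]] <<- c(list(status = status, seed = seed),
                                   list(...))
  }
  need <- function(x, stage, from) {
    if (is.null(x))
      stop("stage '", stage, "' needs the output of stage '", from,
           "' but it was not run", call. = FALSE)
    x
  }

  expr <- markers <- net <- prunedNet <- bulk <- scores <- NULL

  if (on("sc")) {
    sd <- .deriveSeed(config$seed, "sc")
    if (!is.null(config$sc_dir)) {
      expr <- readExpressionDir(config$sc_dir)
      note("sc", "ok", sd, source = config$sc_dir, n_cells = ncol(expr))
    } else {
      cfg <- config$sc_config
      cfg$seed <- sd
      expr <- simulateScCounts(cfg)
      writeExpressionDir(expr, file.path(out_dir, "sc_raw"))
      note("sc", "ok", sd, n_genes = nrow(expr), n_cells = ncol(expr))
    }
  } else note("sc", "skipped")

  if (on("qc")) {
    e <- need(expr, "qc", "sc")
    expr <- filterGenes(filterCells(e, config$qc), config$qc)
    note("qc", "ok", NULL, n_cells = ncol(expr), n_genes = nrow(expr),
         report = metadata(expr)$qc_report[c("n_input", "n_retained",
                                             "n_removed_library",
                                             "n_removed_mito")])
  } else note("qc", "skipped")

  if (on("markers")) {
    e <- need(expr, "markers", "qc")
    markers <- rankMarkers(e, config$markers)
    writeGmt(markers, file.path(out_dir, "markers.gmt"))
    note("markers", "ok", NULL, n_types = length(markers),
         sizes = lengths(markers))
  } else note("markers", "skipped")

  if (on("comm")) {
    e <- need(expr, "comm", "qc")
    sd <- .deriveSeed(config$seed, "comm")
    pairs <- config$lr_pairs
    if (is.null(pairs)) {
      planted <- metadata(e)$truth$lr_plants
      pairs <- do.call(rbind, lapply(planted, function(p)
        data.frame(ligand = p$ligand, receptor = p$receptor,
                   pathway = "planted")))
      set.seed(sd)
      gg <- sample(rownames(e), 2 * config$n_background_pairs)
      pairs <- rbind(pairs, data.frame(
        ligand = gg[seq_len(config$n_background_pairs)],
        receptor = gg[config$n_background_pairs + seq_len(config$n_background_pairs)],
        pathway = "background"))
    }
    st <- commStrength(e, pairs, config$comm)
    net <- aggregateNetwork(st)
    writeEdgeList(net, file.path(out_dir, "network.tsv"))
    note("comm", "ok", sd, n_pairs = nrow(pairs),
         n_edges = nrow(networkEdges(net)))
  } else note("comm", "skipped")

  if (on("hierarchy")) {
    nn <- need(net, "hierarchy", "comm")
    prunedNet <- pruneEdges(nn, config$prune_min_weight)
    root <- findRoot(prunedNet)
    layout <- layerNodes(prunedNet, root)
    jsonlite::write_json(
      list(root = root, layers = as.list(layout@layers),
           unreachable = layout@unreachable,
           threshold = config$prune_min_weight),
      file.path(out_dir, "hierarchy.json"), auto_unbox = TRUE, digits = NA)
    note("hierarchy", "ok", NULL, root = root,
         n_layers = length(unique(layout@layers)))
  } else note("hierarchy", "skipped")

  if (on("motifs")) {
    nn <- if (!is.null(prunedNet)) prunedNet
          else pruneEdges(need(net, "motifs", "comm"), config$prune_min_weight)
    sd <- .deriveSeed(config$seed, "motifs")
    census <- enumerateMotifs(nn, config$motif_sizes)
    writeResultTsv(census, file.path(out_dir, "motif_census.tsv"))
    nc <- config$null
    nc$seed <- sd
    ns <- motifSignificance(nn, nc, config$motif_sizes)
    writeResultTsv(ns, file.path(out_dir, "motif_null.tsv"))
    note("motifs", "ok", sd,
         n_instances = sum(censusTable(census)$count),
         n_random = nc$n_random)
  } else note("motifs", "skipped")

  if (on("bulk")) {
    sd <- .deriveSeed(config$seed, "bulk")
    cfg <- config$bulk_config
    cfg$seed <- sd
    bulk <- simulateBulkMixtures(cfg)
    writeExpressionDir(bulk, file.path(out_dir, "bulk"))
    note("bulk", "ok", sd, n_samples = ncol(bulk))
  } else note("bulk", "skipped")

  if (on("scores")) {
    b <- need(bulk, "scores", "bulk")
    sigs <- metadata(b)$truth$signatures
    scores <- ssgseaScore(b, sigs, config$ssgsea)
    writeResultTsv(scores, file.path(out_dir, "scores.tsv"))
    note("scores", "ok", NULL, n_signatures = ncol(scoreValues(scores)))
  } else note("scores", "skipped")

  if (on("tme")) {
    sc <- need(scores, "tme", "scores")
    sd <- .deriveSeed(config$seed, "tme")
    cc <- config$cluster
    cc$seed <- sd
    assign <- clusterScores(sc, cc)
    assign <- labelSubtypes(assign, config$barrier_sigs, config$exhaustion_sigs)
    writeResultTsv(
      data.frame(sample = names(clusterAssignments(assign)),
                 cluster = clusterAssignments(assign),
                 label = sampleSubtypes(assign)),
      file.path(out_dir, "tme_assignment.tsv"))
    note("tme", "ok", sd, k = assign@k,
         silhouette = round(assign@silhouette, 4))
  } else note("tme", "skipped")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
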