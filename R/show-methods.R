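#' @describeIn CommNetwork compact display.
#' @param object a `CommNetwork`.
#' @export
setMethod("show", "CommNetwork", function(object) {
  cat(sprintf("CommNetwork: %d nodes, %d directed edges\n",
              length(object@nodes), nrow(object@edges)))
  if (nrow(object@edges)) {
    w <- object@edges$weight
    cat(sprintf("  weight range [%.4g, %.4g], total %.4g\n",
                min(w), max(w), sum(w)))
  }
  if (!is.null(object@metadata$prune_threshold))
    cat(sprintf("  pruned at weight < %g\n", object@metadata$prune_threshold))
})

#' @describeIn MotifCensus compact display.
#' @param object a `MotifCensus`.
#' @export
setMethod("show", "MotifCensus", function(object) {
  t <- object@table
  cat(sprintf("MotifCensus over sizes {%s}: %d classes observed\n",
              paste(object@sizes, collapse = ","), sum(t$count > 0)))
  for (k in object@sizes) {
    tk <- t[t$size == k & t$count > 0, , drop = FALSE]
    cat(sprintf("  size %d: %d instances in %d classes, total strength %.4g\n",
                k, sum(tk$count), nrow(tk), sum(tk$strength)))
  }
  if (isTRUE(object@metadata$n_self_loops > 0))
    cat(sprintf("  (%d self-loop(s) excluded from the census)\n",
                object@metadata$n_self_loops))
})

#' @describeIn NullEnsembleStats compact display.
#' @param object a `NullEnsembleStats`.
#' @export
setMethod("show", "NullEnsembleStats", function(object) {
  cat(sprintf("NullEnsembleStats: %d classes vs %d rewired networks\n",
              nrow(object@stats), object@nRandom))
  sig <- object@stats[which(object@stats$p_strength < 0.05), , drop = FALSE]
  cat(sprintf("  %d class(es) with strength p < 0.05\n", nrow(sig)))
})

#' @describeIn ScoreMatrix compact display.
#' @param object a `ScoreMatrix`.
#' @export
setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix [%s]: %d samples x %d signatures (%s)\n",
              object@method, nrow(object@scores), ncol(object@scores),
              object@normalization))
})

#' @describeIn HierarchyLayout compact display.
#' @param object a `HierarchyLayout`.
#' @export
setMethod("show", "HierarchyLayout", function(object) {
  cat(sprintf("HierarchyLayout: root '%s', %d layered node(s), %d unreachable\n",
              object@root, length(object@layers), length(object@unreachable)))
  if (length(object@layers))
    print(split(names(object@layers), object@layers))
})

#' @describeIn TMEAssignment compact display.
#' @param object a `TMEAssignment`.
#' @export
setMethod("show", "TMEAssignment", function(object) {
  cat(sprintf("TMEAssignment: %d samples in k = %d clusters (mean silhouette %.3f%s)\n",
              length(object@clusters), object@k, object@silhouette,
              if (object@weakStructure) ", weak structure" else ""))
  if (length(object@subtypeLabels)) {
    tab <- table(sampleSubtypes(object))
    cat("  subtypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})
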